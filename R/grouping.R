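#' Partition marks into Set I / Set II by PCA
#'
#' Columns of the gene-by-mark matrix are standardized (centred, unit
#' variance) and a PCA is run over marks. Set I collects the marks with the
#' highest contributions to the first \code{n_components} principal
#' components; Set II is the remainder. Two contribution rules are offered:
#' \code{"loading"} (default) takes marks whose absolute loading on any of
#' the leading components exceeds \eqn{1/\sqrt{M}} for \eqn{M} marks (an
#' above-average contribution), \code{"topk"} takes the \code{top_k} largest
#' absolute loadings per component. Constant columns are excluded from the
#' PCA and assigned to Set II with a warning.
#'
#' @param mat numeric gene-by-mark matrix (e.g. from [mark_matrix()]).
#' @param n_components number of leading components defining Set I
#'   (default 4).
#' @param rule \code{"loading"} or \code{"topk"}.
#' @param top_k marks per component under \code{rule = "topk"}.
#' @return An object of class \code{mark_partition}: list with
#'   \code{set_I}, \code{set_II}, \code{loadings} (marks x components) and
#'   \code{variance_explained}.
#' @export
split_sets <- function(mat, n_components = 4L, rule = c("loading", "topk"),
                       top_k = 3L) {
  rule <- match.arg(rule)
  if (is.null(colnames(mat))) stop("mark matrix needs column names",
                                   call. = FALSE)
  if (nrow(mat) < 2L) stop("need at least 2 genes", call. = FALSE)
  const <- apply(mat, 2, function(x) stats::var(x) == 0)
  if (any(const))
    warning("constant column(s) excluded from PCA, assigned to Set II: ",
            paste(colnames(mat)[const], collapse = ", "), call. = FALSE)
  active <- mat[, !const, drop = FALSE]
  if (ncol(active) < n_components)
    stop("need at least ", n_components, " non-constant marks", call. = FALSE)
  pc <- stats::prcomp(active, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  load <- pc$rotation
  k <- min(n_components, ncol(load))
  set_I <- if (rule == "loading") {
    # at-least-average contribution; the tolerance keeps the boundary case
    # (all loadings exactly equal) in Set I
    cut <- 1 / sqrt(ncol(active)) - 1e-9
    colnames(active)[apply(abs(load[, seq_len(k), drop = FALSE]) > cut, 1, any)]
  } else {
    unique(unlist(lapply(seq_len(k), function(j)
      rownames(load)[order(abs(load[, j]), decreasing = TRUE)[seq_len(top_k)]])))
  }
  structure(list(set_I = sort(set_I),
                 set_II = sort(setdiff(colnames(mat), set_I)),
                 loadings = load,
                 variance_explained = ve),
            class = "mark_partition")
}

#' @export
print.mark_partition <- function(x, ...) {
  cat("mark_partition\n  Set I (", length(x$set_I), "): ",
      paste(x$set_I, collapse = ", "), "\n  Set II (", length(x$set_II),
      "): ", paste(x$set_II, collapse = ", "), "\n  variance explained by ",
      "leading components: ", paste(sprintf("%.3f",
      utils::head(x$variance_explained, 4)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Write a mark partition report as JSON
#'
#' @param partition a [split_sets()] result.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_partition <- function(partition, path) {
  obj <- list(set_I = partition$set_I, set_II = partition$set_II,
              variance_explained = partition$variance_explained,
              loadings = as.data.frame(partition$loadings))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
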