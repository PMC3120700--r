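#' Perturb TSS positions to emulate low-resolution promoter annotation
#'
#' Each TSS is shifted by a uniform integer offset in
#' \code{[-max_offset, +max_offset]}, applied in transcript orientation
#' (strand-aware). With the default 150-bp nucleosome spacing, a 500-bp
#' offset displaces a tag's nucleosome assignment by about 1.7 indices on
#' average (a span of roughly 3 nucleosomes).
#'
#' @param genes a \code{gene_models} data.frame.
#' @param max_offset maximum absolute offset in bp (default 500; 0 is the
#'   identity).
#' @param seed integer seed.
#' @return The gene models with perturbed \code{tss}.
#' @export
jitter_tss <- function(genes, max_offset = 500L, seed = 1L) {
  if (max_offset < 0L) stop("max_offset must be >= 0", call. = FALSE)
  if (max_offset == 0L) return(genes)
  rng <- local_rng(seed)
  off <- sample.int(2L * max_offset + 1L, nrow(genes), replace = TRUE) -
    max_offset - 1L
  rng()
  genes$tss <- as.integer(genes$tss +
                            ifelse(genes$strand == "+", off, -off))
  genes
}

#' Scale a feature table to tags-per-million depth
#'
#' Divides each mark's columns by that mark's total tag count in millions,
#' removing sequencing-depth differences before cross-cell-type transfer.
#'
#' @param table a \code{feature_table}.
#' @param totals named numeric vector of per-mark total tag counts (e.g.
#'   \code{sapply(tracks, `[[`, "total")} named by mark).
#' @return A depth-normalized \code{feature_table}.
#' @export
normalize_track_depth <- function(table, totals) {
  marks <- feature_mark(colnames(table$values))
  missing <- setdiff(unique(marks), names(totals))
  if (length(missing))
    stop("no total tag count for mark(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  scale <- totals[marks] / 1e6
  vals <- sweep(table$values, 2, scale, "/")
  feature_table(vals, table$region_kind)
}

#' Cross-dataset transfer evaluation
#'
#' Trains classifiers on balanced resamples of the source table (restricted
#' to the marks shared with the target), applies each to every target gene,
#' and reports metrics against the target labels. When a control table
#' (same featurization at the source's control regions) is supplied, a
#' control-trained baseline is evaluated the same way and compared by
#' rank-sum test on per-replicate F-scores.
#'
#' @param source_table,target_table \code{feature_table}s sharing feature
#'   names for their common marks.
#' @param source_labels,target_labels \code{-1 / +1} vectors aligned to the
#'   table rows.
#' @param replicates,rounds,seed resampling parameters.
#' @param exclude_marks marks removed before training (default none).
#' @param control_table optional control-region \code{feature_table} for the
#'   source genes.
#' @return List of class \code{transfer_report}: per-replicate and mean
#'   metrics for the transferred classifier, the control baseline (if any),
#'   and the signal-vs-control \code{p_value}/\code{symbol}.
#' @export
transfer_evaluate <- function(source_table, source_labels,
                              target_table, target_labels,
                              replicates = 20L, rounds = 100L, seed = 1L,
                              exclude_marks = character(),
                              control_table = NULL) {
  shared <- setdiff(intersect(table_marks(source_table),
                              table_marks(target_table)),
                    exclude_marks)
  if (!length(shared)) stop("no shared marks after exclusion", call. = FALSE)
  src <- restrict_marks(source_table, shared)
  tgt <- restrict_marks(target_table, shared)
  run <- function(train_tab, salt) {
    Xs <- train_tab$values
    per <- matrix(NA_real_, replicates, 3,
                  dimnames = list(NULL,
                                  c("sensitivity", "ppv", "f_score")))
    pos <- which(source_labels == 1)
    neg <- which(source_labels == -1)
    if (length(neg) < length(pos))
      stop("need at least as many source negatives as positives",
           call. = FALSE)
    for (r in seq_len(replicates)) {
      rs <- derive_seed(seed, salt + r)
      rng <- local_rng(rs)
      take <- neg[sample.int(length(neg), length(pos))]
      rng()
      idx <- c(pos, take)
      model <- coreboost(Xs[idx, , drop = FALSE], source_labels[idx],
                         rounds = rounds)
      pred <- predict(model, tgt$values)
      per[r, ] <- metrics(confusion_counts(target_labels, pred))
    }
    list(per_replicate = as.data.frame(per),
         means = colMeans(per, na.rm = TRUE),
         sds = apply(per, 2, stats::sd, na.rm = TRUE))
  }
  out <- list(report = run(src, 100L), shared_marks = shared)
  if (!is.null(control_table)) {
    ctl <- restrict_marks(control_table, shared)
    # control features follow the promoter column schema so control-trained
    # models can score the target promoter table directly; independently
    # seeded resamples keep the rank-sum comparison unpaired
    colnames(ctl$values) <- colnames(src$values)
    out$control_report <- run(ctl, 5000L)
    p <- suppressWarnings(
      stats::wilcox.test(out$report$per_replicate$f_score,
                         out$control_report$per_replicate$f_score,
                         alternative = "two.sided")$p.value)
    out$p_value <- p
    out$symbol <- significance_symbol(p)
  }
  structure(out, class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat("transfer_report on", length(x$shared_marks), "shared mark(s)\n")
  for (m in names(x$report$means))
    cat(sprintf("  %-12s %.3f ± %.3f\n", m, x$report$means[m],
                x$report$sds[m]))
  if (!is.null(x$p_value))
    cat(sprintf("  vs control: p = %.3g %s\n", x$p_value, x$symbol))
  invisible(x)
}

#' Mark-removal redundancy experiment
#'
#' Reruns the balanced-resampling evaluation on the table with the given
#' marks dropped and pairs it with the full-table baseline under the same
#' seed: if the dropped marks' information is redundantly carried by the
#' remaining ones, performance barely moves; dropping the only informative
#' mark collapses it to chance.
#'
#' @param table a \code{feature_table}.
#' @param labels \code{-1 / +1} vector aligned to the table rows.
#' @param drop marks to remove (must be a strict subset of the table's
#'   marks).
#' @param replicates,folds,rounds,seed as in [replicate_experiment()].
#' @return List of class \code{redundancy_report}: \code{full} and
#'   \code{dropped} replicate reports plus \code{delta_f}
#'   (full minus dropped mean F).
#' @export
redundancy_experiment <- function(table, labels, drop, replicates = 20L,
                                  folds = 5L, rounds = 100L, seed = 1L) {
  marks <- table_marks(table)
  unknown <- setdiff(drop, marks)
  if (length(unknown))
    stop("unknown mark(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- setdiff(marks, drop)
  if (!length(keep)) stop("cannot drop every mark", call. = FALSE)
  pos <- table$values[labels == 1, , drop = FALSE]
  neg <- table$values[labels == -1, , drop = FALSE]
  full <- replicate_experiment(pos, neg, replicates = replicates,
                               folds = folds, rounds = rounds, seed = seed)
  red <- restrict_marks(table, keep)
  dropped <- replicate_experiment(red$values[labels == 1, , drop = FALSE],
                                  red$values[labels == -1, , drop = FALSE],
                                  replicates = replicates, folds = folds,
                                  rounds = rounds, seed = seed)
  structure(list(full = full, dropped = dropped,
                 delta_f = full$means[["f_score"]] -
                   dropped$means[["f_score"]],
                 drop = drop),
            class = "redundancy_report")
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat("redundancy_report: dropped ", paste(x$drop, collapse = ", "), "\n",
      sprintf("  mean F full %.3f, dropped %.3f (delta %.3f)\n",
              x$full$means[["f_score"]], x$dropped$means[["f_score"]],
              x$delta_f), sep = "")
  invisible(x)
}
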