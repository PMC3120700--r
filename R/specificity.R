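#' Relative expression of one gene across tissues
#'
#' @param row non-negative per-tissue expression values with positive sum.
#' @return Proportions summing to 1.
#' @export
relative_expression <- function(row) {
  if (any(row < 0)) stop("expression values must be non-negative", call. = FALSE)
  s <- sum(row)
  if (s <= 0)
    stop("specificity undefined for an all-zero expression row", call. = FALSE)
  row / s
}

#' Overall Shannon entropy of an expression profile (bits)
#'
#' \eqn{H = -\sum_t p_t \log_2 p_t} with \eqn{0 \cdot \log 0 \equiv 0}.
#' Low entropy means tissue-specific expression; the maximum
#' \eqn{\log_2 T} is reached at uniform expression over \eqn{T} tissues.
#'
#' @param p proportion vector (see [relative_expression()]).
#' @return Entropy in bits, in \eqn{[0, \log_2 T]}.
#' @export
overall_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Categorical entropy of a gene for one tissue (bits)
#'
#' \eqn{Q_t = H - \log_2 p_t}: always \eqn{\ge H}, equal to \eqn{H} exactly
#' when all expression is in tissue \eqn{t}, and \code{Inf} when the gene is
#' silent there. Low \eqn{Q_t} means specific to tissue \eqn{t}.
#'
#' @param p proportion vector.
#' @param H the overall entropy of \code{p} (bits).
#' @param t tissue index or name.
#' @return \eqn{Q_t} in bits (possibly \code{Inf}).
#' @export
categorical_entropy <- function(p, H, t) {
  pt <- p[t]
  if (length(pt) != 1L || is.na(pt))
    stop("tissue not found in proportion vector", call. = FALSE)
  if (pt == 0) return(Inf)
  H - log2(pt)
}

#' Per-gene specificity scores for a target tissue
#'
#' Computes, for every gene, the overall entropy \code{H}, the categorical
#' entropy \code{Q} for the target tissue, and the z-score \code{z_Q} of
#' \code{Q} across genes oriented so that larger values mean more specific
#' (\code{z_Q = (mean(Q) - Q) / sd(Q)}, over genes with finite \code{Q}).
#'
#' @param expr gene-by-tissue matrix of non-negative values (row/col names
#'   required); genes with zero row sum are dropped with a message.
#' @param target_tissue column name of the tissue of interest.
#' @return data.frame of class \code{specificity_scores} with columns
#'   \code{gene}, \code{H}, \code{Q}, \code{z_Q}.
#' @export
specificity_scores <- function(expr, target_tissue) {
  if (!target_tissue %in% colnames(expr))
    stop("target tissue '", target_tissue, "' not in expression matrix",
         call. = FALSE)
  keep <- rowSums(expr) > 0
  if (any(!keep)) {
    message("dropping ", sum(!keep), " gene(s) with zero total expression")
    expr <- expr[keep, , drop = FALSE]
  }
  p <- expr / rowSums(expr)
  pl <- p
  pl[pl == 0] <- 1                       # 0 log 0 = 0
  H <- -rowSums(p * log2(pl))
  pt <- p[, target_tissue]
  Q <- ifelse(pt > 0, H - log2(pt), Inf)
  fin <- is.finite(Q)
  z <- rep(NA_real_, length(Q))
  if (sum(fin) >= 2L)
    z[fin] <- (mean(Q[fin]) - Q[fin]) / stats::sd(Q[fin])
  out <- data.frame(gene = rownames(expr), H = H, Q = Q, z_Q = z,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("specificity_scores", "data.frame")
  out
}

#' Call tissue-specific genes by entropy thresholds
#'
#' Default mode selects genes with overall entropy below \code{h_max} and
#' categorical entropy (for the target tissue the scores were computed on)
#' below \code{q_max}. The z-score mode instead requires \code{z_Q > z_min}
#' together with the overall-entropy cut.
#'
#' @param scores a [specificity_scores()] data.frame.
#' @param h_max overall entropy ceiling (bits), default 5.0.
#' @param q_max categorical entropy ceiling (bits), default 9.0.
#' @param mode \code{"absolute"} (default) or \code{"zscore"}.
#' @param z_min z-score floor for \code{mode = "zscore"}, default 2.
#' @return Character vector of gene ids.
#' @export
call_specific <- function(scores, h_max = 5.0, q_max = 9.0,
                          mode = c("absolute", "zscore"), z_min = 2) {
  mode <- match.arg(mode)
  keep <- if (mode == "absolute") {
    scores$H < h_max & scores$Q < q_max
  } else {
    scores$H < h_max & !is.na(scores$z_Q) & scores$z_Q > z_min
  }
  scores$gene[keep]
}

#' Call housekeeping genes by dual overall-entropy floors
#'
#' A gene is housekeeping when its overall expression entropy exceeds
#' \code{h_min_a} in the first dataset and \code{h_min_b} in the second
#' (broad expression in both). Scores are intersected on gene id.
#'
#' @param scores_a,scores_b [specificity_scores()] from the two expression
#'   datasets.
#' @param h_min_a,h_min_b entropy floors in bits (defaults 6.2 and 8.9).
#' @return Character vector of gene ids.
#' @export
call_housekeeping <- function(scores_a, scores_b,
                              h_min_a = 6.2, h_min_b = 8.9) {
  common <- intersect(scores_a$gene, scores_b$gene)
  if (!length(common))
    stop("the two score sets share no genes", call. = FALSE)
  ha <- scores_a$H[match(common, scores_a$gene)]
  hb <- scores_b$H[match(common, scores_b$gene)]
  common[ha > h_min_a & hb > h_min_b]
}
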