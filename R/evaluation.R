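#' Confusion counts
#'
#' @param truth,pred \code{-1 / +1} label vectors of equal length, or use
#'   \code{confusion_counts(TP =, FP =, TN =, FN =)} directly.
#' @param TP,FP,TN,FN non-negative integer counts (used when \code{truth}
#'   is missing).
#' @return An object of class \code{confusion_counts}.
#' @export
confusion_counts <- function(truth, pred, TP = 0L, FP = 0L, TN = 0L,
                             FN = 0L) {
  if (!missing(truth)) {
    stopifnot(length(truth) == length(pred))
    TP <- sum(truth == 1 & pred == 1)
    FP <- sum(truth == -1 & pred == 1)
    TN <- sum(truth == -1 & pred == -1)
    FN <- sum(truth == 1 & pred == -1)
  }
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' Sensitivity, PPV and F-score from confusion counts
#'
#' \eqn{Sn = TP/(TP+FN)}, \eqn{PPV = TP/(TP+FP)},
#' \eqn{F = 2 \cdot Sn \cdot PPV / (Sn + PPV)} (0 when \eqn{Sn + PPV = 0}).
#' An undefined denominator yields \code{NA}, never a silent zero.
#'
#' @param counts a [confusion_counts()] object.
#' @return Named numeric vector \code{c(sensitivity, ppv, f_score)}.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  sn <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN)
        else NA_real_
  ppv <- if (counts$TP + counts$FP > 0) counts$TP / (counts$TP + counts$FP)
         else NA_real_
  f <- if (is.na(sn) || is.na(ppv)) NA_real_
       else if (sn + ppv == 0) 0
       else 2 * sn * ppv / (sn + ppv)
  c(sensitivity = sn, ppv = ppv, f_score = f)
}

#' Truncate metrics to two decimals for printed-table comparison
#'
#' Truncation, not rounding (0.1454 renders as 0.14); internal values keep
#' full precision.
#'
#' @param x numeric vector.
#' @return \code{x} truncated to two decimals.
#' @export
truncate2 <- function(x) trunc(x * 100) / 100

#' Stratified k-fold partition
#'
#' Folds are disjoint, cover all samples, differ in size by at most one, and
#' are stratified by class label.
#'
#' @param y class labels (any type).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return Integer vector of fold assignments in \code{1..k}.
#' @export
kfold <- function(y, k = 5L, seed = 1L) {
  n <- length(y)
  if (n < k) stop("fewer samples than folds", call. = FALSE)
  rng <- local_rng(seed)
  fold <- integer(n)
  pos <- 0L
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
    pos <- pos + length(idx)
  }
  rng()
  fold
}

# evaluate a seeded expression under an isolated RNG state; returns a
# restore function (used so exported functions do not disturb the caller's
# RNG stream)
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}

# deterministic child seed below 2^31
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt * 16807) %% 2147483647) + 1L
}

#' k-fold cross-validation of the boosting classifier
#'
#' Each sample is tested exactly once; the reported metrics are the mean of
#' the per-fold metrics (folds with an undefined metric are dropped from
#' that mean).
#'
#' @param X feature matrix.
#' @param y labels in \code{-1 / +1}.
#' @param k folds (default 5).
#' @param seed integer seed for the fold partition.
#' @param rounds boosting rounds per fold model.
#' @return List of class \code{cv_result}: \code{mean} (named metric
#'   vector), \code{per_fold} (data.frame), \code{pooled}
#'   ([confusion_counts()] over all test predictions).
#' @export
cross_validate <- function(X, y, k = 5L, seed = 1L, rounds = 100L) {
  check_labels(y)
  fold <- kfold(y, k, seed)
  pred <- numeric(length(y))
  per_fold <- matrix(NA_real_, k, 3,
                     dimnames = list(NULL, c("sensitivity", "ppv", "f_score")))
  for (i in seq_len(k)) {
    te <- fold == i
    model <- coreboost(X[!te, , drop = FALSE], y[!te], rounds = rounds)
    pred[te] <- predict(model, X[te, , drop = FALSE])
    per_fold[i, ] <- metrics(confusion_counts(y[te], pred[te]))
  }
  structure(list(
    mean = colMeans(per_fold, na.rm = TRUE),
    per_fold = as.data.frame(per_fold),
    pooled = confusion_counts(y, pred)
  ), class = "cv_result")
}

#' Balanced-resampling replicate experiment
#'
#' The class imbalance between positives and negatives is removed by
#' resampling: each replicate draws \code{|pos|} negatives without
#' replacement, runs a stratified k-fold cross-validation on the balanced
#' set, and trains a final model on the whole balanced set whose round-1
#' stump feature is recorded as the replicate's top predictive feature.
#' Metrics are aggregated as means and standard deviations over replicates,
#' together with per-feature (and per-mark) top-selection counts.
#'
#' @param pos,neg positive/negative class rows: \code{feature_table}s or
#'   matrices sharing column names. Requires \code{nrow(neg) >= nrow(pos)}.
#' @param replicates number of resampling replicates (default 100).
#' @param folds cross-validation folds (default 5).
#' @param rounds boosting rounds.
#' @param seed master seed; the report is exactly reproducible given it.
#' @return List of class \code{replicate_report}: \code{per_replicate}
#'   (data.frame of sensitivity/ppv/f_score), \code{means}, \code{sds},
#'   \code{top_counts} (feature-level), \code{mark_counts} (mark-level),
#'   \code{replicates}.
#' @export
replicate_experiment <- function(pos, neg, replicates = 100L, folds = 5L,
                                 rounds = 100L, seed = 1L) {
  Xp <- if (inherits(pos, "feature_table")) pos$values else as.matrix(pos)
  Xn <- if (inherits(neg, "feature_table")) neg$values else as.matrix(neg)
  if (!identical(colnames(Xp), colnames(Xn)))
    stop("positive and negative tables must share feature names",
         call. = FALSE)
  if (nrow(Xn) < nrow(Xp))
    stop("need at least as many negatives as positives", call. = FALSE)
  np <- nrow(Xp)
  per <- matrix(NA_real_, replicates, 3,
                dimnames = list(NULL, c("sensitivity", "ppv", "f_score")))
  top <- character(replicates)
  for (r in seq_len(replicates)) {
    rs <- derive_seed(seed, r)
    rng <- local_rng(rs)
    take <- sample.int(nrow(Xn), np)
    rng()
    X <- rbind(Xp, Xn[take, , drop = FALSE])
    y <- rep(c(1, -1), each = np)
    cv <- cross_validate(X, y, k = folds, seed = derive_seed(rs, 1L),
                         rounds = rounds)
    per[r, ] <- cv$mean
    final <- coreboost(X, y, rounds = rounds)
    top[r] <- final$stumps$feature[1]
  }
  top_counts <- sort(table(top), decreasing = TRUE)
  mark_counts <- sort(table(feature_mark(top)), decreasing = TRUE)
  structure(list(
    per_replicate = as.data.frame(per),
    means = colMeans(per, na.rm = TRUE),
    sds = apply(per, 2, stats::sd, na.rm = TRUE),
    top_counts = top_counts,
    mark_counts = mark_counts,
    replicates = replicates
  ), class = "replicate_report")
}

#' @export
print.replicate_report <- function(x, ...) {
  cat("replicate_report over ", x$replicates, " balanced resamples\n",
      sep = "")
  for (m in names(x$means))
    cat(sprintf("  %-12s %.3f ± %.3f\n", m, x$means[m], x$sds[m]))
  cat("  top feature counts: ",
      paste(names(utils::head(x$top_counts, 5)),
            utils::head(x$top_counts, 5), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a replicate report summary as JSON
#'
#' @param report a [replicate_experiment()] result.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_replicate_report <- function(report, path) {
  obj <- list(replicates = report$replicates,
              means = as.list(report$means), sds = as.list(report$sds),
              top_counts = as.list(report$top_counts),
              mark_counts = as.list(report$mark_counts),
              per_replicate = report$per_replicate)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

significance_symbol <- function(p) {
  if (p < 1e-5) "" else if (p < 1e-2) "*" else "†"
}

#' Compare signal and control replicate reports
#'
#' Two-sided Wilcoxon rank-sum test on per-replicate F-scores, with the
#' printed-table significance symbols: no symbol for \eqn{p < 10^{-5}},
#' \code{*} for \eqn{p < 0.01}, and a dagger for \eqn{p \ge 0.01}.
#'
#' @param report_signal,report_control [replicate_experiment()] results with
#'   equal replicate counts.
#' @return List with \code{p_value}, \code{symbol} and the mean F-scores.
#' @export
compare_to_control <- function(report_signal, report_control) {
  a <- report_signal$per_replicate$f_score
  b <- report_control$per_replicate$f_score
  if (length(a) != length(b))
    stop("replicate counts differ", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 replicates", call. = FALSE)
  # ties between replicate scores force the normal approximation; that is
  # expected, not worth a warning
  p <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
  list(p_value = p, symbol = significance_symbol(p),
       mean_f_signal = mean(a, na.rm = TRUE),
       mean_f_control = mean(b, na.rm = TRUE))
}

#' Per-gene correlation between two marks' promoter profiles
#'
#' Pearson correlation across nucleosome positions between two genes x
#' nucleosome profile matrices (e.g. one mark's promoter columns each).
#' Genes with a constant profile in either mark have undefined correlation
#' and are excluded with a count.
#'
#' @param profile_a,profile_b numeric matrices of equal dimensions (genes x
#'   nucleosomes), or \code{feature_table}s holding a single mark each.
#' @return List with \code{r} (per-gene), \code{median_r} and
#'   \code{n_excluded}.
#' @export
profile_correlation <- function(profile_a, profile_b) {
  A <- if (inherits(profile_a, "feature_table")) profile_a$values else profile_a
  B <- if (inherits(profile_b, "feature_table")) profile_b$values else profile_b
  if (!all(dim(A) == dim(B)))
    stop("profiles must have equal dimensions", call. = FALSE)
  ok <- apply(A, 1, stats::sd) > 0 & apply(B, 1, stats::sd) > 0
  r <- rep(NA_real_, nrow(A))
  r[ok] <- vapply(which(ok), function(i) stats::cor(A[i, ], B[i, ]),
                  numeric(1))
  list(r = stats::setNames(r, rownames(A)),
       median_r = stats::median(r[ok]),
       n_excluded = sum(!ok))
}

#' Rank-sum comparison of regional densities between two gene sets
#'
#' Two-sided Wilcoxon rank-sum test on [regional_signal_density()] values,
#' with figure-style stars: \code{**} for \eqn{p < 10^{-4}}, \code{*} for
#' \eqn{p < 0.05}, none otherwise.
#'
#' @param densities_a,densities_b numeric density vectors (non-empty).
#' @return List with \code{p_value} and \code{stars}.
#' @export
compare_gene_sets <- function(densities_a, densities_b) {
  if (!length(densities_a) || !length(densities_b))
    stop("gene sets must be non-empty", call. = FALSE)
  p <- suppressWarnings(
    stats::wilcox.test(densities_a, densities_b,
                       alternative = "two.sided")$p.value)
  stars <- if (p < 1e-4) "**" else if (p < 0.05) "*" else ""
  list(p_value = p, stars = stars)
}

#' Evaluate an externally defined predicted gene set
#'
#' Treats membership in \code{predicted} as the positive prediction and in
#' \code{truth_pos} as the positive truth over a common gene universe, and
#' computes confusion counts and metrics, plus the two-decimal truncated
#' rendering used for printed-table comparison.
#'
#' @param predicted,truth_pos character vectors of gene ids (subsets of
#'   \code{universe}).
#' @param universe character vector of all gene ids considered.
#' @return List with \code{confusion}, \code{metrics} and \code{truncated}.
#' @export
evaluate_external_geneset <- function(predicted, truth_pos, universe) {
  if (!all(predicted %in% universe) || !all(truth_pos %in% universe))
    stop("predicted and truth sets must lie within the universe",
         call. = FALSE)
  tp <- length(intersect(predicted, truth_pos))
  fp <- length(setdiff(predicted, truth_pos))
  fn <- length(setdiff(truth_pos, predicted))
  tn <- length(universe) - tp - fp - fn
  cc <- confusion_counts(TP = tp, FP = fp, TN = tn, FN = fn)
  m <- metrics(cc)
  list(confusion = cc, metrics = m, truncated = truncate2(m))
}

#' Null band of the mean F-score under label shuffling
#'
#' Repeatedly permutes the labels, cross-validates, and returns the central
#' band of the resulting F-scores: the reference distribution for "no
#' signal" on a given feature table.
#'
#' @param X feature matrix.
#' @param y labels in \code{-1 / +1}.
#' @param replicates label permutations (default 20).
#' @param folds,rounds,seed as in [cross_validate()].
#' @param level central coverage of the band (default 0.99).
#' @return List with \code{f_scores}, \code{band} (two quantiles) and
#'   \code{mean_f}.
#' @export
shuffled_label_band <- function(X, y, replicates = 20L, folds = 5L,
                                rounds = 100L, seed = 1L, level = 0.99) {
  f <- numeric(replicates)
  for (r in seq_len(replicates)) {
    rs <- derive_seed(seed, 1000L + r)
    rng <- local_rng(rs)
    ys <- y[sample.int(length(y))]
    rng()
    f[r] <- cross_validate(X, ys, k = folds, seed = derive_seed(rs, 2L),
                           rounds = rounds)$mean[["f_score"]]
  }
  alpha <- (1 - level) / 2
  list(f_scores = f,
       band = stats::quantile(f, c(alpha, 1 - alpha), names = FALSE),
       mean_f = mean(f))
}
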