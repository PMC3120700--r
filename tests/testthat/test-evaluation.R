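test_that("metrics match direct formulas, including the printed worked case", {
  expect_equal(metrics(confusion_counts(TP = 10L, FP = 0L, FN = 0L)),
               c(sensitivity = 1, ppv = 1, f_score = 1))
  expect_equal(metrics(confusion_counts(TP = 0L, FP = 5L, FN = 5L)),
               c(sensitivity = 0, ppv = 0, f_score = 0))

  m <- metrics(confusion_counts(TP = 66L, FP = 326L, FN = 388L))
  expect_equal(unname(m), c(66 / 454, 66 / 392,
                            2 * (66 / 454) * (66 / 392) /
                              (66 / 454 + 66 / 392)))
  expect_equal(unname(truncate2(m)), c(0.14, 0.16, 0.15))

  # undefined denominators yield NA, never a silent zero
  und <- metrics(confusion_counts(TP = 0L, FP = 0L, FN = 0L, TN = 5L))
  expect_true(all(is.na(und)))

  # property: every small confusion table agrees with the direct formulas
  for (tp in c(0L, 1L, 7L, 20L)) for (fp in 0:20) for (fn in c(0L, 3L, 20L)) {
    got <- metrics(confusion_counts(TP = tp, FP = fp, FN = fn))
    sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    pv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f <- if (is.na(sn) || is.na(pv)) NA_real_
         else if (sn + pv == 0) 0 else 2 * sn * pv / (sn + pv)
    expect_identical(unname(got), c(sn, pv, f))
  }
})

test_that("stratified folds are balanced, covering and reproducible", {
  y <- rep(c(1, -1), 5)
  f <- kfold(y, k = 5, seed = 3)
  expect_equal(as.vector(table(f)), rep(2L, 5))
  expect_setequal(unique(f), 1:5)
  expect_identical(kfold(y, k = 5, seed = 3), f)
  expect_false(identical(kfold(y, k = 5, seed = 4), f))
  # stratification: each fold carries one sample of each class here
  for (i in 1:5) expect_setequal(y[f == i], c(1, -1))
  expect_error(kfold(y[1:3], k = 5), "fewer samples")
})

test_that("cross-validation tests every sample once and detects signal", {
  d <- planted_matrix(n_pos = 50, n_neg = 50, delta = 4, seed = 13)
  cv <- cross_validate(d$X, d$y, k = 5, seed = 1, rounds = 10)
  expect_gte(cv$mean[["f_score"]], 0.95)
  pooled <- cv$pooled
  expect_equal(pooled$TP + pooled$FP + pooled$TN + pooled$FN, 100L)
  expect_equal(pooled$TP + pooled$FN, 50L)
})

test_that("balanced resampling reports are seed-reproducible and coherent", {
  d <- small_design(seed = 14L)
  labels <- hmvboost:::design_labels(d)
  gen <- simulate_genome(d)
  tracks <- simulate_tags(d, gen$genes, labels)
  ft <- promoter_features(gen$genes, tracks)
  pos <- ft$values[labels == "specific", ]
  neg <- ft$values[labels == "housekeeping", ]

  r1 <- replicate_experiment(pos, neg, replicates = 6, folds = 5,
                             rounds = 10, seed = 2)
  r2 <- replicate_experiment(pos, neg, replicates = 6, folds = 5,
                             rounds = 10, seed = 2)
  expect_identical(r1, r2)

  expect_gte(r1$means[["f_score"]], min(r1$per_replicate$f_score))
  expect_lte(r1$means[["f_score"]], max(r1$per_replicate$f_score))
  expect_lte(sum(r1$top_counts), r1$replicates)

  # the planted informative mark dominates top-feature selection
  expect_equal(names(r1$mark_counts)[1], "M01")
  expect_error(replicate_experiment(neg, pos), "as many negatives")
})

test_that("signal-vs-control comparison applies the symbol bands", {
  mk <- function(f) structure(list(per_replicate = data.frame(f_score = f)),
                              class = "replicate_report")
  same <- mk(rep(c(0.8, 0.9), 10))
  expect_equal(suppressWarnings(compare_to_control(same, same)$p_value), 1)

  set.seed(15)
  hi <- mk(runif(100, 0.8, 0.9)); lo <- mk(runif(100, 0.4, 0.5))
  cmp <- compare_to_control(hi, lo)
  expect_lt(cmp$p_value, 1e-5)
  expect_equal(cmp$symbol, "")
  expect_equal(hmvboost:::significance_symbol(5e-3), "*")
  expect_equal(hmvboost:::significance_symbol(0.2), "†")
  expect_error(compare_to_control(mk(1), mk(1)), "at least 2")
  expect_error(compare_to_control(hi, mk(runif(5))), "replicate counts")
})

test_that("profile correlations handle identity, negation and noise", {
  set.seed(16)
  A <- matrix(rnorm(200 * 26), 200, 26)
  expect_equal(unname(profile_correlation(A, A)$r), rep(1, 200))
  neg <- profile_correlation(A, -A + 2)
  expect_equal(unname(neg$r), rep(-1, 200))
  B <- matrix(rnorm(200 * 26), 200, 26)
  ind <- profile_correlation(A, B)
  expect_lt(abs(ind$median_r), 0.15)
  # constant profiles are excluded with a count
  A2 <- A; A2[1, ] <- 3
  expect_equal(profile_correlation(A2, B)$n_excluded, 1L)
  expect_error(profile_correlation(A, B[, 1:10]), "equal dimensions")
})

test_that("gene-set density comparison stars follow the figure thresholds", {
  set.seed(17)
  a <- rnorm(80, 1); b <- rnorm(80, 0)
  cmp <- compare_gene_sets(a, b)
  expect_lt(cmp$p_value, 1e-4)
  expect_equal(cmp$stars, "**")
  weak <- suppressWarnings(compare_gene_sets(c(1, 2, 3, 4), c(2, 3, 4, 5)))
  expect_equal(weak$stars, "")
  expect_error(compare_gene_sets(numeric(0), a), "non-empty")
})

test_that("external gene-set evaluation reproduces the printed triple", {
  universe <- paste0("g", 1:1500)
  truth <- universe[1:454]
  predicted <- c(universe[1:66], universe[500:825])  # overlap 66, size 392
  ev <- evaluate_external_geneset(predicted, truth, universe)
  expect_equal(ev$confusion$TP, 66L)
  expect_equal(length(predicted), 392L)
  expect_equal(unname(ev$truncated), c(0.14, 0.16, 0.15))

  expect_equal(unname(evaluate_external_geneset(truth, truth,
                                                universe)$metrics),
               c(1, 1, 1))
  disjoint <- evaluate_external_geneset(universe[1000:1100], truth, universe)
  expect_equal(unname(disjoint$metrics[["f_score"]]), 0)
  expect_error(evaluate_external_geneset("nope", truth, universe),
               "within the universe")
})
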