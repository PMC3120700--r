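test_that("design validation enforces the planted-structure invariants", {
  expect_error(simulation_design(k = 79, n_tissues = 79), "smaller than")
  expect_error(simulation_design(base_rate = 0), "positive")
  expect_error(simulation_design(f = 0.5), ">= 1")
  expect_error(simulation_design(informative = data.frame(
    mark = "H3K4me3", region = "promoter")), "among the design's marks")
})

test_that("noiseless expression plants exact entropy values", {
  d <- simulation_design(n_specific = 5L, n_housekeeping = 5L,
                         n_tissues = 16L, n_tissues_b = 32L, k = 1L,
                         n_marks = 2L, expression_noise = 0, seed = 2L)
  e <- simulate_expression(d)
  s <- specificity_scores(e$dataset_a, e$target_tissue)
  spec <- e$labels == "specific"
  # k = 1, no noise: point mass -> H = 0; uniform housekeeping -> log2 T
  expect_equal(s$H[spec[s$gene]], rep(0, 5))
  expect_equal(s$H[!spec[s$gene]], rep(log2(16), 5))
  expect_equal(s$Q[spec[s$gene]], rep(0, 5))
})

test_that("the noisy default expression panels recover planted sets", {
  d <- simulation_design(n_specific = 20L, n_housekeeping = 30L,
                         n_marks = 2L, seed = 3L)
  e <- simulate_expression(d)
  expect_equal(dim(e$dataset_a), c(50L, 79L))
  expect_equal(dim(e$dataset_b), c(50L, 600L))
  expect_true(all(e$dataset_a >= 0))
  sa <- specificity_scores(e$dataset_a, e$target_tissue)
  sb <- specificity_scores(e$dataset_b, colnames(e$dataset_b)[1])
  expect_setequal(call_specific(sa),
                  names(e$labels)[e$labels == "specific"])
  expect_setequal(call_housekeeping(sa, sb),
                  names(e$labels)[e$labels == "housekeeping"])
})

test_that("the toy genome respects CpG placement and control clearance", {
  d <- simulation_design(n_specific = 15L, n_housekeeping = 15L,
                         n_marks = 2L, cpg_fraction = 1, seed = 4L)
  gen <- simulate_genome(d)
  expect_true(all(classify_cpg(gen$genes, gen$islands)))
  d$cpg_fraction <- 0
  gen0 <- simulate_genome(d)
  expect_false(any(classify_cpg(gen0$genes, gen0$islands)))
  d$cpg_fraction <- 0.5
  gen5 <- simulate_genome(d)
  expect_equal(classify_cpg(gen5$genes, gen5$islands),
               unname(gen5$cpg_truth))
  # every control anchor clears the chromosome start; genes do not overlap
  tss <- gen$genes$tss
  expect_true(all(pmin(tss - 50000L, tss + 50000L) - 970L >= 1L |
                    gen$genes$strand == "-"))
  o <- order(gen$genes$txstart)
  expect_true(all(gen$genes$txstart[o][-1] >
                    gen$genes$txend[o][-length(o)]))
})

test_that("planted tag effects hit the intended cells at the stated fold", {
  d <- simulation_design(n_specific = 150L, n_housekeeping = 150L,
                         n_marks = 3L, f = 8,
                         informative = data.frame(mark = "M01",
                                                  region = "promoter",
                                                  stringsAsFactors = FALSE),
                         redundancy_groups = list(), seed = 5L)
  labels <- hmvboost:::design_labels(d)
  gen <- simulate_genome(d)
  tracks <- simulate_tags(d, gen$genes, labels)
  ft <- promoter_features(gen$genes, tracks)
  spec <- labels == "specific"

  # class mean ratio at an informative core nucleosome is ~ f
  ratio <- mean(ft$values[spec, "M01_p1"]) / mean(ft$values[!spec, "M01_p1"])
  expect_gt(ratio, 6); expect_lt(ratio, 10)
  # a non-informative mark shows no class difference (alpha = 0.001)
  p <- stats::wilcox.test(ft$values[spec, "M02_p1"],
                          ft$values[!spec, "M02_p1"])$p.value
  expect_gt(p, 0.001)
  # nucleosomes outside the planted core stay null for the informative mark
  p_out <- stats::wilcox.test(ft$values[spec, "M01_m4"],
                              ft$values[!spec, "M01_m4"])$p.value
  expect_gt(p_out, 0.001)
})

test_that("a null design (f = 1) plants no class signal anywhere", {
  d <- simulation_design(n_specific = 100L, n_housekeeping = 100L,
                         n_marks = 2L, f = 1, seed = 6L)
  labels <- hmvboost:::design_labels(d)
  gen <- simulate_genome(d)
  ft <- promoter_features(gen$genes, simulate_tags(d, gen$genes, labels))
  spec <- labels == "specific"
  p <- vapply(c("M01_p1", "M01_p3", "M02_p1"), function(cl)
    stats::wilcox.test(ft$values[spec, cl], ft$values[!spec, cl])$p.value,
    numeric(1))
  expect_true(all(p > 0.001))
})

test_that("counts approach Poisson dispersion as overdispersion vanishes", {
  d <- simulation_design(n_specific = 200L, n_housekeeping = 200L,
                         n_marks = 1L, f = 1, dispersion = Inf,
                         informative = NULL, seed = 7L)
  labels <- hmvboost:::design_labels(d)
  gen <- simulate_genome(d)
  ft <- promoter_features(gen$genes, simulate_tags(d, gen$genes, labels))
  x <- ft$values[, "M01_p2"]
  expect_lt(abs(var(x) / mean(x) - 1), 0.35)

  # finite dispersion is visibly overdispersed: var/mean ~ 1 + mu/size
  d2 <- simulation_design(n_specific = 200L, n_housekeeping = 200L,
                          n_marks = 1L, f = 1, dispersion = 2,
                          informative = NULL, seed = 7L)
  ft2 <- promoter_features(gen$genes,
                           simulate_tags(d2, gen$genes, labels))
  x2 <- ft2$values[, "M01_p2"]
  expect_gt(var(x2) / mean(x2), 1.8)
})

test_that("redundancy groups correlate their marks beyond class structure", {
  d <- simulation_design(n_specific = 200L, n_housekeeping = 100L,
                         n_marks = 3L,
                         informative = data.frame(
                           mark = c("M01", "M02"),
                           region = c("promoter", "promoter"),
                           stringsAsFactors = FALSE),
                         redundancy_groups = list(c("M01", "M02")),
                         p_active = 0.6, seed = 8L)
  labels <- hmvboost:::design_labels(d)
  gen <- simulate_genome(d)
  ft <- promoter_features(gen$genes, simulate_tags(d, gen$genes, labels))
  spec <- labels == "specific"
  sum_core <- function(mark) rowSums(
    ft$values[spec, paste0(mark, "_p", 1:5)])
  # within the specific class, grouped marks co-activate; an ungrouped mark
  # does not correlate with either
  expect_gt(cor(sum_core("M01"), sum_core("M02")), 0.5)
  expect_lt(abs(cor(sum_core("M01"), sum_core("M03"))), 0.25)
})

test_that("dataset bundles are deterministic and feed the readers", {
  d <- simulation_design(n_specific = 10L, n_housekeeping = 15L,
                         n_marks = 2L, seed = 9L)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  b1 <- make_dataset(d, dir1)
  b2 <- make_dataset(d, dir2)
  for (nm in c("expression_a", "genes", "islands", "labels", "config")) {
    expect_identical(readLines(b1$paths[[nm]]), readLines(b2$paths[[nm]]))
  }
  expect_identical(readLines(b1$paths$tags[1]), readLines(b2$paths$tags[1]))

  genes <- read_gene_models(b1$paths$genes)
  direct <- simulate_genome(d)$genes
  expect_equal(genes$tss, direct$tss)
  expect_equal(genes$strand, direct$strand)
  expect_equal(genes$exons, direct$exons)

  tr <- read_tag_track(b1$paths$tags[1], "M01")
  direct_tr <- simulate_tags(d, direct,
                             hmvboost:::design_labels(d))[[1]]
  expect_equal(tr$total, direct_tr$total)

  expr <- read_expression_matrix(b1$paths$expression_a)
  expect_equal(dim(expr), c(25L, 79L))
  islands <- read_bed_intervals(b1$paths$islands)
  expect_true(nrow(islands) > 0)
  cfg <- read_config(b1$paths$config)
  expect_equal(cfg$seed, 9L)
})
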