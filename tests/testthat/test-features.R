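test_that("nucleosome grid reproduces the printed anchors and extensions", {
  grid <- nucleosome_grid()
  expect_equal(nrow(grid), 26L)
  expect_equal(grid$index, c(-6:-1, 1:20))
  anchors <- data.frame(
    index = c(-2L, -1L, 1L, 2L, 3L, 4L, 5L),
    start = c(-370L, -195L, -45L, 135L, 315L, 495L, 675L),
    end   = c(-196L, -46L, 134L, 314L, 494L, 674L, 859L))
  for (i in seq_len(nrow(anchors))) {
    row <- grid[grid$index == anchors$index[i], ]
    expect_equal(c(row$start, row$end),
                 c(anchors$start[i], anchors$end[i]))
  }
  # extensions are 150-bp and abut their inner neighbour
  expect_equal(unlist(grid[grid$index == -3, c("start", "end")]),
               c(start = -520, end = -371))
  expect_equal(unlist(grid[grid$index == 6, c("start", "end")]),
               c(start = 860, end = 1009))
  ext <- grid$index <= -3 | grid$index >= 6
  expect_true(all(grid$end[ext] - grid$start[ext] + 1L == 150L))
  expect_true(all(diff(grid$start) == grid$end[-26] - grid$start[-26] + 1L))
  # alternate promoter extent -6..+9
  expect_equal(nrow(nucleosome_grid(6, 9)), 15L)
})

test_that("TSS-relative coordinates mirror on the minus strand", {
  expect_equal(to_relative(1005, 1000, "+"), 5)
  expect_equal(to_relative(995, 1000, "-"), 5)
  # the TSS base itself falls in nucleosome +1
  grid <- nucleosome_grid()
  expect_equal(hmvboost:::grid_index(0, grid), 1L)
  expect_equal(hmvboost:::grid_index(-46, grid), -1L)
  expect_equal(hmvboost:::grid_index(3110, grid), NA_integer_)
})

test_that("CpG classification uses the strand-aware [-2kb, +500] window", {
  g <- make_genes(c("p", "m"), strand = c("+", "-"),
                  tss = c(10000L, 10000L), txstart = c(10000L, 5000L),
                  txend = c(15000L, 10000L))
  # 400-500 bp upstream of the plus gene, within 500 bp downstream of the
  # minus gene: inside both windows
  inside <- data.frame(chrom = "chr1", start = 9500L, end = 9600L)
  expect_equal(classify_cpg(g, inside), c(TRUE, TRUE))
  far <- data.frame(chrom = "chr1", start = 6900L, end = 6999L)
  expect_equal(classify_cpg(g, far), c(FALSE, FALSE))
  # 1-bp overlap at the window edge counts; window edges differ by strand
  edge_plus <- data.frame(chrom = "chr1", start = 7000L, end = 8000L)
  expect_equal(classify_cpg(g, edge_plus), c(TRUE, FALSE))
  edge_minus <- data.frame(chrom = "chr1", start = 12000L, end = 12000L)
  expect_equal(classify_cpg(g, edge_minus), c(FALSE, TRUE))
})

test_that("promoter featurization counts anchors per nucleosome", {
  g <- make_genes("g1", tss = 100000L, txstart = 100000L, txend = 103000L)
  empty <- promoter_features(g, list(track_at("M01", numeric(0))))
  expect_true(all(empty$values == 0))
  expect_equal(dim(empty$values), c(1L, 26L))

  tr <- track_at("M01", 100000)        # one tag exactly at the TSS
  ft <- promoter_features(g, list(tr))
  expect_equal(sum(ft$values), 1)
  expect_equal(unname(ft$values[1, "M01_p1"]), 1)

  tr3 <- track_at("M01", 100000 + c(-200, -100, 700))
  ft3 <- promoter_features(g, list(tr3))
  hits <- ft3$values[1, ft3$values[1, ] > 0]
  expect_equal(hits, c(M01_m2 = 1, M01_m1 = 1, M01_p5 = 1))
})

test_that("promoter counts conserve tags against a brute-force scan", {
  set.seed(21)
  grid <- nucleosome_grid()
  genes <- make_genes(paste0("g", 1:6), strand = rep(c("+", "-"), 3),
                      tss = seq(50000L, 300000L, length.out = 6),
                      txstart = seq(50000L, 300000L, length.out = 6) - 2000L,
                      txend = seq(50000L, 300000L, length.out = 6) + 8000L)
  pos <- sort(sample(40000:310000, 5000))
  tr <- track_at("M01", pos)
  ft <- promoter_features(genes, list(tr), grid)
  for (i in seq_len(nrow(genes))) {
    rel <- to_relative(pos, genes$tss[i], genes$strand[i])
    direct <- sum(rel >= min(grid$start) & rel <= max(grid$end))
    expect_equal(sum(ft$values[i, ]), direct)
  }
})

test_that("featurization is invariant to strand mirroring and input order", {
  set.seed(22)
  L <- 400000L
  genes <- make_genes(c("a", "b"), strand = c("+", "-"),
                      tss = c(100000L, 203000L),
                      txstart = c(100000L, 200000L),
                      txend = c(103000L, 203000L))
  tracks <- list(track_at("M01", sample(90000:210000, 3000)),
                 track_at("M02", sample(90000:210000, 2000)))
  ft <- promoter_features(genes, tracks)

  # mirror the genome: position -> L + 1 - position, strands flipped
  mirror_genes <- make_genes(c("a", "b"), strand = c("-", "+"),
                             tss = L + 1L - c(100000L, 203000L),
                             txstart = L + 1L - c(103000L, 203000L),
                             txend = L + 1L - c(100000L, 200000L))
  mirror_tracks <- lapply(tracks, function(tr)
    track_at(tr$mark, L + 1 - tr$tags$chr1))
  mft <- promoter_features(mirror_genes, mirror_tracks)
  expect_equal(mft$values, ft$values)

  # permuting gene order or track order permutes rows, nothing else
  perm <- promoter_features(genes[2:1, ], rev(tracks))
  expect_equal(perm$values, ft$values[2:1, ])
})

test_that("body features compute region sums, densities and tiled windows", {
  g <- one_gene("+")   # exon1 100000..100999, intron 101000..102000,
                       # exon2 102001..103000
  zero <- body_features(g, list(track_at("M01", numeric(0))))
  expect_true(all(zero$values == 0))
  expect_equal(dim(zero$values), c(1L, 7L))

  # 10 tags spread in the 1000-bp first exon: sum 10, avg 0.01/bp
  tr <- track_at("M01", seq(100000, 100999, length.out = 10))
  ft <- body_features(g, list(tr))
  v <- ft$values[1, ]
  expect_equal(unname(v["M01_1stExon_sum"]), 10)
  expect_equal(unname(v["M01_1stExon_avg"]), 0.01)
  expect_equal(unname(v["M01_1stIntron_sum"]), 0)
  expect_equal(unname(v["M01_body_sum"]), 10)
  expect_equal(unname(v["M01_body_avg"]), 10 / 3001)

  # post-first-exon windows truncate at the transcript end: a tag past the
  # end never counts, a tag in the truncated final window does
  tr2 <- track_at("M01", c(102950, 103500))
  ft2 <- body_features(g, list(tr2))
  expect_equal(unname(ft2$values[1, "M01_postExon1_sum"]), 1)

  # minus-strand gene: first exon is the high-coordinate one
  gm <- one_gene("-")
  trm <- track_at("M01", c(102500, 100500))
  ftm <- body_features(gm, list(trm))
  expect_equal(unname(ftm$values[1, "M01_1stExon_sum"]), 1)
  expect_equal(unname(ftm$values[1, "M01_postExon1_sum"]), 1)

  # intronless gene is flagged and gets zero intron features
  gi <- make_genes("solo", tss = 50000L, txstart = 50000L, txend = 51000L)
  fti <- body_features(gi, list(track_at("M01", 50500)))
  expect_true(attr(fti, "intronless")[["solo"]])
  expect_equal(unname(fti$values[1, "M01_1stIntron_sum"]), 0)
})

test_that("control features move the anchor 50 kb transcript-upstream", {
  g <- make_genes("g1", tss = 100000L, txstart = 100000L, txend = 103000L)
  # a tag at the control anchor lands in the control +1 nucleosome
  tr <- track_at("M01", 50000)
  cf <- control_features(g, list(tr))
  expect_equal(cf$region_kind, "control")
  expect_equal(unname(cf$values[1, "M01_p1"]), 1)
  # the same tag is nowhere near the promoter table
  expect_true(all(promoter_features(g, list(tr))$values == 0))

  # genes whose control anchor falls off the chromosome are dropped
  g2 <- make_genes(c("ok", "low"), tss = c(100000L, 10000L),
                   txstart = c(100000L, 10000L), txend = c(103000L, 13000L))
  expect_warning(cf2 <- control_features(g2, list(tr)), "dropped")
  expect_equal(rownames(cf2$values), "ok")
})

test_that("regional densities are length- and expression-controlled", {
  g <- make_genes("g1", tss = 10000L, txstart = 10000L, txend = 11999L)
  tr <- track_at("M01", seq(10000, 11999, length.out = 20))
  expect_equal(unname(regional_signal_density(g, tr, "exonic")), 0.01)
  expect_equal(unname(regional_signal_density(g, tr, "exonic",
                                              expression = 2)), 0.005)
  expect_error(regional_signal_density(g, tr, "intronic"), "zero-length")
  expect_equal(unname(regional_signal_density(g, track_at("M01", numeric(0)),
                                              "body")), 0)
})

test_that("mark restriction preserves order and validates names", {
  set.seed(9)
  marks <- sprintf("M%02d", 1:5)
  cols <- unlist(lapply(marks, function(m) paste0(m, "_p", 1:26)))
  ft <- feature_table(matrix(rpois(10 * 130, 2), 10, 130,
                             dimnames = list(paste0("g", 1:10), cols)),
                      "promoter")
  expect_equal(restrict_marks(ft, marks)$values, ft$values)
  sub <- restrict_marks(ft, c("M02", "M04"))
  expect_equal(ncol(sub$values), 2L * 26L)
  expect_equal(colnames(sub$values),
               cols[hmvboost:::feature_mark(cols) %in% c("M02", "M04")])
  expect_error(restrict_marks(ft, character(0)), "zero marks")
  expect_error(restrict_marks(ft, "H3K4me3"), "unknown mark")
})

test_that("the mark matrix counts tags in the 4-kb TSS window", {
  g <- make_genes("g1", tss = 100000L, txstart = 100000L, txend = 105000L)
  tr <- track_at("M01", c(100000 + 1999, 100000 + 2001, 100000 - 2000))
  mm <- mark_matrix(g, list(tr))
  expect_equal(unname(mm[1, 1]), 2)
})
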