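# shared fixture builders; everything is generated in code

# gene_models data.frame from bare fields; exons defaults to the whole span
make_genes <- function(id, chrom = "chr1", strand = "+", tss, txstart, txend,
                       exons = NULL) {
  n <- length(id)
  strand <- rep_len(strand, n)
  chrom <- rep_len(chrom, n)
  recs <- lapply(seq_len(n), function(i) {
    ex <- if (is.null(exons)) {
      cbind(start = txstart[i], end = txend[i])
    } else exons[[i]]
    list(id = id[i], chrom = chrom[i], strand = strand[i], tss = tss[i],
         txstart = txstart[i], txend = txend[i], exons = ex)
  })
  hmvboost:::build_gene_models(recs)
}

# a single multi-exon gene with known geometry
one_gene <- function(strand = "+", tss = 100000L) {
  if (strand == "+") {
    exons <- list(cbind(start = c(100000L, 102001L),
                        end = c(100999L, 103000L)))
    make_genes("g1", strand = "+", tss = tss, txstart = 100000L,
               txend = 103000L, exons = exons)
  } else {
    # transcript orientation: first exon at the high-coordinate end
    exons <- list(cbind(start = c(102001L, 100000L),
                        end = c(103000L, 100999L)))
    make_genes("g1", strand = "-", tss = 103000L, txstart = 100000L,
               txend = 103000L, exons = exons)
  }
}

# tag track with tags at given 1-based positions on one chromosome
track_at <- function(mark, pos, chrom = "chr1") {
  tag_track(mark, stats::setNames(list(pos), chrom))
}

# brute-force stump oracle: enumerate every (feature, threshold, polarity)
# and score by direct prediction; same tie order as the implementation
oracle_stump <- function(X, y, w = NULL) {
  n <- nrow(X)
  if (is.null(w)) w <- rep(1 / n, n)
  w <- w / sum(w)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    xs <- sort(unique(x))
    thrs <- c(-Inf, (xs[-length(xs)] + xs[-1]) / 2, Inf)
    for (thr in thrs) {
      for (pol in c(1, -1)) {
        pred <- pol * (2 * (x > thr) - 1)
        err <- sum(w[pred != y])
        if (is.null(best) || err < best$error - 1e-15) {
          best <- list(index = j, threshold = thr, polarity = pol,
                       error = err)
        }
      }
    }
  }
  best
}

# direct weighted error of a stump by prediction
stump_error <- function(s, X, y, w = NULL) {
  n <- nrow(X)
  if (is.null(w)) w <- rep(1 / n, n)
  w <- w / sum(w)
  pred <- s$polarity * (2 * (X[, s$index] > s$threshold) - 1)
  sum(w[pred != y])
}

# small planted-signal classification matrix: first column shifted by delta
# for the positive class, the rest standard normal noise
planted_matrix <- function(n_pos = 40, n_neg = 40, p = 6, delta = 3,
                           seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n_pos + n_neg) * p), n_pos + n_neg, p,
              dimnames = list(NULL, paste0("F", seq_len(p), "_p1")))
  y <- rep(c(1, -1), c(n_pos, n_neg))
  X[y == 1, 1] <- X[y == 1, 1] + delta
  list(X = X, y = y)
}

# balanced matrix/labels: all positives plus an equal-size seeded draw of
# negatives (mirrors the balanced-resampling evaluation)
balanced_xy <- function(values, pos_ids, neg_ids, seed = 1) {
  set.seed(seed)
  take <- sample(neg_ids, length(pos_ids))
  X <- values[c(pos_ids, take), , drop = FALSE]
  list(X = X, y = rep(c(1, -1), each = length(pos_ids)))
}

# compact design for fast end-to-end tests
small_design <- function(..., seed = 11L) {
  simulation_design(n_specific = 60L, n_housekeeping = 90L, n_marks = 6L,
                    informative = data.frame(mark = "M01",
                                             region = "promoter",
                                             stringsAsFactors = FALSE),
                    redundancy_groups = list(), seed = seed, ...)
}
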