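#' Feature table container
#'
#' A gene-by-feature matrix of tag counts or statistics with structured
#' feature names (\code{<mark>_m6..<mark>_p20} for promoter/control tables;
#' \code{<mark>_1stExon_sum}, \code{_1stExon_avg}, \code{_1stIntron_sum},
#' \code{_1stIntron_avg}, \code{_body_sum}, \code{_body_avg},
#' \code{_postExon1_sum} for body tables).
#'
#' @param values numeric matrix with gene ids as row names and feature names
#'   as column names.
#' @param region_kind one of \code{"promoter"}, \code{"body"},
#'   \code{"control"}.
#' @return An object of class \code{feature_table}.
#' @export
feature_table <- function(values, region_kind = c("promoter", "body",
                                                  "control")) {
  region_kind <- match.arg(region_kind)
  stopifnot(is.matrix(values))
  if (anyDuplicated(colnames(values)))
    stop("feature names must be unique", call. = FALSE)
  structure(list(values = values, region_kind = region_kind),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table (", x$region_kind, "): ", nrow(x$values), " genes x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# mark name of each structured feature name
feature_mark <- function(features) {
  sub("_(m\\d+|p\\d+|1stExon_(sum|avg)|1stIntron_(sum|avg)|body_(sum|avg)|postExon1_sum)$",
      "", features)
}

#' Marks present in a feature table
#' @param table a \code{feature_table}.
#' @return Character vector of mark names.
#' @export
table_marks <- function(table) unique(feature_mark(colnames(table$values)))

#' Restrict a feature table to a subset of marks
#'
#' Keeps only the columns belonging to the given marks, preserving column
#' order.
#'
#' @param table a \code{feature_table}.
#' @param marks character vector of mark names (must all be present).
#' @return A \code{feature_table}.
#' @export
restrict_marks <- function(table, marks) {
  have <- table_marks(table)
  if (!length(marks)) stop("cannot restrict to zero marks", call. = FALSE)
  unknown <- setdiff(marks, have)
  if (length(unknown))
    stop("unknown mark(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  keep <- feature_mark(colnames(table$values)) %in% marks
  feature_table(table$values[, keep, drop = FALSE], table$region_kind)
}

# tags of one track on one chromosome falling in [lo, hi] (sorted vector)
tags_between <- function(track, chrom, lo, hi) {
  v <- track$tags[[chrom]]
  if (is.null(v) || !length(v)) return(numeric(0))
  i <- findInterval(c(lo - 1, hi), v)
  if (i[2] <= i[1]) return(numeric(0))
  v[(i[1] + 1):i[2]]
}

count_between <- function(track, chrom, lo, hi) {
  v <- track$tags[[chrom]]
  if (is.null(v)) return(0L)
  i <- findInterval(c(lo - 1, hi), v)
  i[2] - i[1]
}

# vectorized closed-interval counts; chrom aligned with lo/hi
counts_by_chrom <- function(track, chrom, lo, hi) {
  out <- numeric(length(lo))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    v <- track$tags[[ch]]
    if (is.null(v) || !length(v)) next
    out[sel] <- findInterval(hi[sel], v) - findInterval(lo[sel] - 1, v)
  }
  out
}

warn_missing_chroms <- function(track, chroms) {
  missing_chr <- setdiff(unique(chroms), names(track$tags))
  if (length(missing_chr))
    warning("track '", track$mark, "' lacks chromosome(s): ",
            paste(missing_chr, collapse = ", "), "; features set to 0",
            call. = FALSE)
}

nucleosome_feature_names <- function(mark, grid) {
  paste0(mark, "_", ifelse(grid$index < 0, paste0("m", -grid$index),
                           paste0("p", grid$index)))
}

# shared worker for promoter and control tables: counts tag anchors of every
# track in the TSS-relative grid intervals around per-gene anchor positions.
# Counting is batched: one findInterval pair per (track, chromosome) over
# the flattened genes x intervals bound matrices.
anchored_features <- function(genes, tracks, grid, anchors, region_kind) {
  marks <- vapply(tracks, `[[`, "", "mark")
  ord <- order(marks)
  tracks <- tracks[ord]
  marks <- marks[ord]
  if (anyDuplicated(marks)) stop("duplicate mark names", call. = FALSE)
  nk <- nrow(grid)
  n <- nrow(genes)
  plus <- genes$strand == "+"
  # genomic bounds of each gene's grid intervals (mirrored on minus strand)
  lo <- outer(anchors, grid$start, `+`)
  hi <- outer(anchors, grid$end, `+`)
  lo[!plus, ] <- outer(anchors[!plus], grid$end, `-`)
  hi[!plus, ] <- outer(anchors[!plus], grid$start, `-`)
  chrom <- rep(genes$chrom, times = nk)
  vals <- matrix(0, nrow = n, ncol = nk * length(marks),
                 dimnames = list(genes$id, unlist(
                   lapply(marks, nucleosome_feature_names, grid = grid))))
  for (m in seq_along(tracks)) {
    tr <- tracks[[m]]
    warn_missing_chroms(tr, genes$chrom)
    cnt <- counts_by_chrom(tr, chrom, as.vector(lo), as.vector(hi))
    vals[, (m - 1L) * nk + seq_len(nk)] <- cnt
  }
  feature_table(vals, region_kind)
}

#' Promoter feature table on the nucleosome grid
#'
#' For every gene and mark, the tag-anchor count in each TSS-relative
#' nucleosome interval (the mark's level on that nucleosome). Columns are
#' ordered marks-alphabetical, nucleosome index ascending, giving
#' \code{26 * M} columns for \code{M} marks under the default grid.
#'
#' @param genes a \code{gene_models} data.frame.
#' @param tracks list of [tag_track()] objects (one per mark).
#' @param grid a [nucleosome_grid()].
#' @return A \code{feature_table} with \code{region_kind = "promoter"}.
#' @export
promoter_features <- function(genes, tracks, grid = nucleosome_grid()) {
  anchored_features(genes, tracks, grid, genes$tss, "promoter")
}

#' Control-region feature table
#'
#' Identical featurization to [promoter_features()] with the anchor moved
#' \code{offset} bp transcript-upstream of the TSS (a null locus). Genes
#' whose control anchor would fall before position 1 are dropped with a
#' warning.
#'
#' @inheritParams promoter_features
#' @param offset control-site distance in bp (default 50000).
#' @return A \code{feature_table} with \code{region_kind = "control"}.
#' @export
control_features <- function(genes, tracks, grid = nucleosome_grid(),
                             offset = 50000L) {
  anchors <- ifelse(genes$strand == "+", genes$tss - offset,
                    genes$tss + offset)
  ok <- anchors >= 1L
  if (any(!ok)) {
    warning(sum(!ok), " gene(s) dropped: control anchor before chromosome",
            " start", call. = FALSE)
    genes <- genes[ok, , drop = FALSE]
    anchors <- anchors[ok]
  }
  anchored_features(genes, tracks, grid, anchors, "control")
}

body_feature_names <- function(mark) {
  paste0(mark, "_", c("1stExon_sum", "1stExon_avg", "1stIntron_sum",
                      "1stIntron_avg", "body_sum", "body_avg",
                      "postExon1_sum"))
}

# first intron of a gene in transcript orientation, or NULL
first_intron <- function(gene_exons, strand) {
  if (nrow(gene_exons) < 2L) return(NULL)
  e1 <- gene_exons[1, ]; e2 <- gene_exons[2, ]
  if (strand == "+") c(e1["end"] + 1L, e2["start"] - 1L)
  else c(e2["end"] + 1L, e1["start"] - 1L)
}

# twenty 150-bp windows tiled transcript-downstream from the first exon's
# 3' end, truncated at the transcript end; windows entirely past the end
# are omitted (they contribute zero counts)
post_exon1_windows <- function(gene, n_windows = 20L, width = 150L) {
  ex1 <- gene$exons[[1]]
  if (gene$strand == "+") {
    s0 <- ex1[1, "end"] + 1L
    lo <- s0 + width * (seq_len(n_windows) - 1L)
    hi <- pmin(lo + width - 1L, gene$txend)
    keep <- lo <= gene$txend
  } else {
    s0 <- ex1[1, "start"] - 1L
    hi <- s0 - width * (seq_len(n_windows) - 1L)
    lo <- pmax(hi - width + 1L, gene$txstart)
    keep <- hi >= gene$txstart
  }
  cbind(lo = lo[keep], hi = hi[keep])
}

#' Gene-body feature table
#'
#' Per mark and gene: sum and per-bp average of the mark's level over the
#' first exon, the first intron and the whole gene body (first = 5'-most in
#' transcript orientation), plus the summed count over twenty 150-bp windows
#' tiled transcript-downstream from the first exon's 3' end (truncated at
#' the transcript end). Intronless genes get zero first-intron features and
#' are flagged in the \code{"intronless"} attribute.
#'
#' @inheritParams promoter_features
#' @return A \code{feature_table} with \code{region_kind = "body"} and 7
#'   columns per mark.
#' @export
body_features <- function(genes, tracks, grid = nucleosome_grid()) {
  marks <- vapply(tracks, `[[`, "", "mark")
  ord <- order(marks)
  tracks <- tracks[ord]
  marks <- marks[ord]
  n <- nrow(genes)
  vals <- matrix(0, nrow = n, ncol = 7L * length(marks),
                 dimnames = list(genes$id,
                                 unlist(lapply(marks, body_feature_names))))
  intronless <- vapply(genes$exons, nrow, integer(1)) < 2L
  # per-gene region bounds, computed once
  ex_lo <- vapply(genes$exons, function(e) e[1, "start"], numeric(1))
  ex_hi <- vapply(genes$exons, function(e) e[1, "end"], numeric(1))
  len1 <- ex_hi - ex_lo + 1
  intr <- lapply(seq_len(n), function(g)
    first_intron(genes$exons[[g]], genes$strand[g]))
  has_in <- !vapply(intr, is.null, logical(1)) &
    vapply(intr, function(x) is.null(x) || x[2] >= x[1], logical(1))
  in_lo <- ifelse(has_in, vapply(intr, function(x)
    if (is.null(x)) NA_real_ else x[1], numeric(1)), 1)
  in_hi <- ifelse(has_in, vapply(intr, function(x)
    if (is.null(x)) NA_real_ else x[2], numeric(1)), 0)
  len_i <- pmax(in_hi - in_lo + 1, 0)
  len_b <- genes$txend - genes$txstart + 1
  wins <- lapply(seq_len(n), function(g)
    post_exon1_windows(genes[g, , drop = FALSE]))
  w_gene <- rep(seq_len(n), vapply(wins, nrow, integer(1)))
  w_lo <- unlist(lapply(wins, function(w) w[, "lo"]))
  w_hi <- unlist(lapply(wins, function(w) w[, "hi"]))
  for (m in seq_along(tracks)) {
    tr <- tracks[[m]]
    warn_missing_chroms(tr, genes$chrom)
    s_ex <- counts_by_chrom(tr, genes$chrom, ex_lo, ex_hi)
    s_in <- counts_by_chrom(tr, genes$chrom, in_lo, in_hi)
    s_in[!has_in] <- 0
    s_b <- counts_by_chrom(tr, genes$chrom, genes$txstart, genes$txend)
    s_w <- numeric(n)
    if (length(w_gene)) {
      w_cnt <- counts_by_chrom(tr, genes$chrom[w_gene], w_lo, w_hi)
      agg <- rowsum(w_cnt, w_gene)
      s_w[as.integer(rownames(agg))] <- agg[, 1]
    }
    vals[, (m - 1L) * 7L + 1:7] <- cbind(
      s_ex, s_ex / len1,
      s_in, ifelse(len_i > 0, s_in / len_i, 0),
      s_b, s_b / len_b,
      s_w)
  }
  ft <- feature_table(vals, "body")
  attr(ft, "intronless") <- stats::setNames(intronless, genes$id)
  ft
}

#' Length-controlled regional tag density
#'
#' Tag count over a gene's exonic, intronic or whole-body region divided by
#' the region length (per-bp density), optionally further divided by an
#' expression level.
#'
#' @param genes a \code{gene_models} data.frame (one or more genes).
#' @param track a [tag_track()].
#' @param region \code{"exonic"}, \code{"intronic"} or \code{"body"}.
#' @param expression optional per-gene expression level used as a second
#'   normalizer.
#' @return Numeric vector of densities, one per gene.
#' @export
regional_signal_density <- function(genes, track,
                                    region = c("exonic", "intronic", "body"),
                                    expression = NULL) {
  region <- match.arg(region)
  out <- vapply(seq_len(nrow(genes)), function(g) {
    chrom <- genes$chrom[g]
    ivs <- switch(region,
      exonic = genes$exons[[g]],
      body = cbind(start = genes$txstart[g], end = genes$txend[g]),
      intronic = {
        ex <- genes$exons[[g]]
        ex <- ex[order(ex[, "start"]), , drop = FALSE]
        if (nrow(ex) < 2L) matrix(integer(0), 0, 2,
                                  dimnames = list(NULL, c("start", "end")))
        else cbind(start = ex[-nrow(ex), "end"] + 1L,
                   end = ex[-1L, "start"] - 1L)
      })
    len <- if (nrow(ivs)) sum(ivs[, 2] - ivs[, 1] + 1L) else 0L
    if (len <= 0L)
      stop("zero-length ", region, " region for gene ", genes$id[g],
           call. = FALSE)
    n <- sum(vapply(seq_len(nrow(ivs)), function(i)
      count_between(track, chrom, ivs[i, 1], ivs[i, 2]), integer(1)))
    n / len
  }, numeric(1))
  if (!is.null(expression)) out <- out / expression
  stats::setNames(out, genes$id)
}

#' Gene-by-mark matrix of TSS-proximal tag sums
#'
#' Entry \code{(g, m)} is the count of mark \code{m}'s tag anchors within
#' \code{halfwidth} bp of gene \code{g}'s TSS (default the 4 kb window
#' \code{[-2000, +2000]}). Input for the PCA-based mark grouping.
#'
#' @inheritParams promoter_features
#' @param halfwidth window half-width in bp.
#' @return Numeric matrix, genes in rows, marks in columns.
#' @export
mark_matrix <- function(genes, tracks, halfwidth = 2000L) {
  marks <- sort(vapply(tracks, `[[`, "", "mark"))
  tracks <- tracks[order(vapply(tracks, `[[`, "", "mark"))]
  vals <- matrix(0, nrow(genes), length(tracks),
                 dimnames = list(genes$id, marks))
  for (m in seq_along(tracks)) {
    vals[, m] <- counts_by_chrom(tracks[[m]], genes$chrom,
                                 genes$tss - halfwidth,
                                 genes$tss + halfwidth)
  }
  vals
}
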