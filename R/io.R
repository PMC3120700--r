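#' Read gene models from BED12 or GTF
#'
#' Each transcript record becomes one gene model carrying its TSS (the
#' transcript 5' end: the higher genomic coordinate for minus-strand
#' transcripts), strand, span and exon structure. Genomic coordinates are
#' handled internally as 1-based closed; BED input (0-based half-open) is
#' converted on ingest.
#'
#' @param path path to a BED12 (or, with \pkg{rtracklayer} installed, GTF)
#'   file.
#' @param format \code{"auto"} guesses from the file extension.
#' @return A data.frame of class \code{gene_models} with columns \code{id},
#'   \code{chrom}, \code{strand}, \code{tss}, \code{txstart}, \code{txend},
#'   \code{cpg_related} (logical, \code{NA} until classified) and a list
#'   column \code{exons} (two-column start/end matrices, ordered 5' to 3' in
#'   transcript orientation).
#' @export
read_gene_models <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.gtf$|\\.gff[23]?$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  if (format == "gtf") return(read_gene_models_gtf(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (!length(lines)) stop("no gene records in ", path, call. = FALSE)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L)
      stop("malformed BED12 record at line ", i, ": expected 12 fields, got ",
           length(f), call. = FALSE)
    start0 <- suppressWarnings(as.integer(f[2]))
    end0 <- suppressWarnings(as.integer(f[3]))
    n_blocks <- suppressWarnings(as.integer(f[10]))
    if (anyNA(c(start0, end0, n_blocks)))
      stop("malformed BED12 record at line ", i, ": non-numeric coordinate",
           call. = FALSE)
    if (start0 < 0L)
      stop("malformed BED12 record at line ", i, ": negative coordinate",
           call. = FALSE)
    strand <- f[6]
    if (!strand %in% c("+", "-"))
      stop("malformed BED12 record at line ", i, ": strand must be + or -",
           call. = FALSE)
    sizes <- as.integer(strsplit(f[11], ",")[[1]])
    offs <- as.integer(strsplit(f[12], ",")[[1]])
    if (length(sizes) != n_blocks || length(offs) != n_blocks)
      stop("malformed BED12 record at line ", i,
           ": blockCount disagrees with block lists", call. = FALSE)
    ex_start <- start0 + offs + 1L           # to 1-based closed
    ex_end <- start0 + offs + sizes
    exons <- cbind(start = ex_start, end = ex_end)
    if (strand == "-") exons <- exons[rev(seq_len(n_blocks)), , drop = FALSE]
    recs[[i]] <- list(
      id = f[4], chrom = f[1], strand = strand,
      tss = if (strand == "+") start0 + 1L else end0,
      txstart = start0 + 1L, txend = end0, exons = exons
    )
  }
  build_gene_models(recs)
}

read_gene_models_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GTF ingest requires the rtracklayer package", call. = FALSE)
  gr <- as.data.frame(rtracklayer::import(path))
  ex <- gr[gr$type == "exon", , drop = FALSE]
  if (!nrow(ex)) stop("no exon records in ", path, call. = FALSE)
  recs <- lapply(split(ex, as.character(ex$transcript_id)), function(e) {
    strand <- as.character(e$strand)[1]
    o <- order(e$start)
    exons <- cbind(start = e$start[o], end = e$end[o])
    if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
    list(id = as.character(e$transcript_id)[1],
         chrom = as.character(e$seqnames)[1],
         strand = strand,
         tss = if (strand == "+") min(e$start) else max(e$end),
         txstart = min(e$start), txend = max(e$end), exons = exons)
  })
  build_gene_models(recs[order(names(recs))])
}

build_gene_models <- function(recs) {
  g <- data.frame(
    id = vapply(recs, `[[`, "", "id"),
    chrom = vapply(recs, `[[`, "", "chrom"),
    strand = vapply(recs, `[[`, "", "strand"),
    tss = vapply(recs, function(r) as.integer(r$tss), integer(1)),
    txstart = vapply(recs, function(r) as.integer(r$txstart), integer(1)),
    txend = vapply(recs, function(r) as.integer(r$txend), integer(1)),
    cpg_related = NA,
    stringsAsFactors = FALSE
  )
  g$exons <- lapply(recs, `[[`, "exons")
  class(g) <- c("gene_models", "data.frame")
  g
}

#' Read a tag track from BED
#'
#' Each sequenced-tag interval is reduced to a single anchor coordinate:
#' its midpoint (default; robust to unknown read length) or its 5' end.
#' BED 0-based half-open intervals are converted to 1-based closed on
#' ingest, so an interval written as \code{[100, 135)} spans 1-based
#' positions 101..135 and anchors at 118 under the midpoint rule.
#'
#' @param path BED file (strand column optional; required for
#'   \code{anchor = "five_prime"} on minus-strand tags).
#' @param mark_name name of the histone modification/variant.
#' @param anchor \code{"midpoint"} or \code{"five_prime"}.
#' @return An object of class \code{tag_track}: list with \code{mark},
#'   \code{tags} (per-chromosome sorted coordinate vectors) and
#'   \code{total} (tag count).
#' @export
read_tag_track <- function(path, mark_name,
                           anchor = c("midpoint", "five_prime")) {
  anchor <- match.arg(anchor)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  empty <- length(readLines(path, n = 1L)) == 0L
  if (empty) return(tag_track(mark_name, list()))
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED needs >= 3 columns: ", path, call. = FALSE)
  if (!is.numeric(bed[[2]]) || !is.numeric(bed[[3]]))
    stop("non-numeric coordinates in ", path, call. = FALSE)
  if (any(bed[[2]] < 0L)) {
    ln <- which(bed[[2]] < 0L)[1]
    stop("negative coordinate at record ", ln, " of ", path, call. = FALSE)
  }
  s1 <- bed[[2]] + 1L
  e1 <- bed[[3]]
  pos <- if (anchor == "midpoint") {
    (s1 + e1) %/% 2L
  } else {
    str <- if (ncol(bed) >= 6L) bed[[6]] else "+"
    ifelse(str == "-", e1, s1)
  }
  tag_track(mark_name, split(pos, bed[[1]]))
}

#' Construct a tag track from per-chromosome coordinates
#'
#' @param mark_name mark name.
#' @param tags named list of numeric coordinate vectors (one per
#'   chromosome); sorted on construction.
#' @return A \code{tag_track}.
#' @export
tag_track <- function(mark_name, tags) {
  tags <- lapply(tags, function(x) sort(as.numeric(x)))
  if (any(vapply(tags, function(x) length(x) && x[1] <= 0, logical(1))))
    stop("tag coordinates must be positive", call. = FALSE)
  structure(list(mark = mark_name, tags = tags,
                 total = sum(lengths(tags))),
            class = "tag_track")
}

#' @export
print.tag_track <- function(x, ...) {
  cat("tag_track '", x$mark, "': ", x$total, " tags on ",
      length(x$tags), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Read simple BED intervals (e.g. CpG islands)
#'
#' @param path BED file.
#' @return data.frame with \code{chrom}, \code{start}, \code{end}
#'   (1-based closed).
#' @export
read_bed_intervals <- function(path) {
  if (length(readLines(path, n = 1L)) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(chrom = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]])
}

#' Write / read a feature table as TSV
#'
#' The first line is a comment carrying the region kind, the header holds
#' the structured feature names, and each row starts with the gene id.
#' The pair is a lossless round trip.
#'
#' @param table a \code{feature_table}.
#' @param path file path.
#' @return \code{read_feature_table} returns a \code{feature_table};
#'   \code{write_feature_table} returns \code{path} invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#region_kind=", table$region_kind), con)
  writeLines(paste(c("gene", colnames(table$values)), collapse = "\t"), con)
  if (nrow(table$values)) {
    body <- apply(table$values, 1, function(r) paste(r, collapse = "\t"))
    writeLines(paste(rownames(table$values), body, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  region <- "promoter"
  if (length(lines) && startsWith(lines[1], "#region_kind=")) {
    region <- sub("^#region_kind=", "", lines[1])
    lines <- lines[-1]
  }
  if (!length(lines)) stop("empty feature table file: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  feats <- header[-1]
  rows <- lines[-1]
  vals <- matrix(numeric(0), nrow = 0, ncol = length(feats),
                 dimnames = list(NULL, feats))
  ids <- character(0)
  if (length(rows)) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != length(header))
    if (length(bad))
      stop("row ", bad[1], " has ", lengths(parts)[bad[1]],
           " fields; header has ", length(header), call. = FALSE)
    ids <- vapply(parts, `[[`, "", 1L)
    num <- suppressWarnings(
      vapply(parts, function(p) as.numeric(p[-1]), numeric(length(feats))))
    if (anyNA(num)) stop("non-numeric cell in ", path, call. = FALSE)
    vals <- matrix(if (length(feats) == 1L) num else t(num),
                   nrow = length(ids), ncol = length(feats),
                   dimnames = list(ids, feats))
  }
  feature_table(vals, region)
}

#' Persist / reload a boosting model as JSON
#'
#' Stumps, weights and feature names are serialized so that transfer
#' experiments can reload a model across runs.
#'
#' @param model a [coreboost] model.
#' @param path file path.
#' @return \code{read_boost_model} returns a \code{coreboost} model;
#'   \code{write_boost_model} returns \code{path} invisibly.
#' @export
write_boost_model <- function(model, path) {
  stopifnot(inherits(model, "coreboost"))
  obj <- list(feature_names = model$feature_names,
              rounds_trained = model$rounds_trained,
              stumps = model$stumps)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_boost_model
#' @export
read_boost_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stumps <- as.data.frame(obj$stumps, stringsAsFactors = FALSE)
  structure(list(stumps = stumps,
                 feature_names = obj$feature_names,
                 rounds_trained = as.integer(obj$rounds_trained)),
            class = "coreboost")
}

# BED writers used by make_dataset ------------------------------------------

write_tags_bed <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$tags)) {
    p <- track$tags[[chrom]]
    if (length(p))
      writeLines(paste(chrom, p - 1L, p, sep = "\t"), con)
  }
  invisible(path)
}

write_genes_bed12 <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    o <- order(ex[, 1])            # BED blocks are in genomic order
    ex <- ex[o, , drop = FALSE]
    start0 <- genes$txstart[i] - 1L
    paste(genes$chrom[i], start0, genes$txend[i], genes$id[i], 0L,
          genes$strand[i], start0, genes$txend[i], "0",
          nrow(ex),
          paste0(paste(ex[, 2] - ex[, 1] + 1L, collapse = ","), ","),
          paste0(paste(ex[, 1] - 1L - start0, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

write_bed_intervals <- function(df, path) {
  if (nrow(df)) {
    writeLines(paste(df$chrom, df$start - 1L, df$end, sep = "\t"), path)
  } else {
    file.create(path)
  }
  invisible(path)
}

#' Read a gene-by-tissue expression matrix from TSV
#'
#' Values below \code{floor} are clipped up to it (microarray noise floor);
#' genes whose row sum is zero before clipping are dropped with a message.
#'
#' @param path TSV with a header of tissue labels and gene ids in the first
#'   column.
#' @param floor clip floor applied on ingest (default 1.0); set to 0 to
#'   disable.
#' @return Numeric matrix, genes in rows, tissues in columns.
#' @export
read_expression_matrix <- function(path, floor = 1.0) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric expression values in ", path,
                           call. = FALSE)
  m[m < 0] <- 0
  zero <- rowSums(m) == 0
  if (any(zero)) {
    message("dropping ", sum(zero), " gene(s) with zero total expression")
    m <- m[!zero, , drop = FALSE]
  }
  if (floor > 0) m[m < floor] <- floor
  m
}

write_expression_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
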