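#' TSS-relative nucleosome grid
#'
#' Fixed intervals approximating nucleosome positions around the TSS, in
#' 1-based closed TSS-relative coordinates (position 0 is the TSS base and
#' falls inside nucleosome +1). The core positions are anchored at
#' -2 [-370, -196], -1 [-195, -46], +1 [-45, 134], +2 [135, 314],
#' +3 [315, 494], +4 [495, 674] and +5 [675, 859]; nucleosomes beyond the
#' anchors extend their inner neighbour by 150 bp. The default extent is the
#' 6th nucleosome upstream to the 20th downstream (26 intervals).
#'
#' @param upstream number of upstream nucleosomes (>= 2).
#' @param downstream number of downstream nucleosomes (>= 5).
#' @return A data.frame of class \code{nucleosome_grid} with columns
#'   \code{index} (-upstream..-1, 1..downstream), \code{start}, \code{end}.
#' @export
nucleosome_grid <- function(upstream = 6L, downstream = 20L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  if (upstream < 2L || downstream < 5L)
    stop("grid must cover at least the anchored nucleosomes -2..+5", call. = FALSE)
  anchors <- data.frame(
    index = c(-2L, -1L, 1L, 2L, 3L, 4L, 5L),
    start = c(-370L, -195L, -45L, 135L, 315L, 495L, 675L),
    end   = c(-196L, -46L, 134L, 314L, 494L, 674L, 859L)
  )
  up <- anchors[anchors$index < 0L, ]
  if (upstream > 2L) {
    for (i in 3L:upstream) {
      inner <- up[up$index == -(i - 1L), ]
      up <- rbind(data.frame(index = -i, start = inner$start - 150L,
                             end = inner$start - 1L), up)
    }
  }
  down <- anchors[anchors$index > 0L, ]
  if (downstream > 5L) {
    for (i in 6L:downstream) {
      inner <- down[down$index == i - 1L, ]
      down <- rbind(down, data.frame(index = i, start = inner$end + 1L,
                                     end = inner$end + 150L))
    }
  }
  grid <- rbind(up, down)
  rownames(grid) <- NULL
  class(grid) <- c("nucleosome_grid", "data.frame")
  grid
}

#' Convert a genomic coordinate to a TSS-relative coordinate
#'
#' Downstream always means transcript direction: on the plus strand the
#' relative coordinate is \code{pos - tss}, on the minus strand it is
#' \code{tss - pos} (mirrored).
#'
#' @param pos genomic coordinate(s), 1-based.
#' @param tss the gene's TSS (1-based genomic).
#' @param strand \code{"+"} or \code{"-"}.
#' @return Integer TSS-relative coordinate(s).
#' @export
to_relative <- function(pos, tss, strand) {
  if (identical(strand, "+")) pos - tss
  else if (identical(strand, "-")) tss - pos
  else stop("strand must be '+' or '-'", call. = FALSE)
}

#' Classify promoters as CpG-related
#'
#' A promoter is CpG-related if a CpG island overlaps the strand-aware
#' window from 2 kb upstream to 500 bp downstream of the TSS.
#'
#' @param genes a \code{gene_models} data.frame (see [read_gene_models()]).
#' @param islands data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based closed genomic intervals).
#' @param upstream,downstream window extent in bp (defaults 2000 and 500).
#' @return Logical vector, one entry per gene.
#' @export
classify_cpg <- function(genes, islands, upstream = 2000L, downstream = 500L) {
  plus <- genes$strand == "+"
  win_lo <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  win_hi <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  vapply(seq_len(nrow(genes)), function(i) {
    isl <- islands[islands$chrom == genes$chrom[i], , drop = FALSE]
    any(isl$start <= win_hi[i] & isl$end >= win_lo[i])
  }, logical(1))
}

# nucleosome index of a TSS-relative coordinate; NA outside the grid.
# The grid intervals are contiguous, so a single findInterval suffices.
grid_index <- function(rel, grid) {
  breaks <- c(grid$start, grid$end[nrow(grid)] + 1L)
  bin <- findInterval(rel, breaks)
  bin[bin < 1L | bin > nrow(grid)] <- NA_integer_
  grid$index[bin]
}
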