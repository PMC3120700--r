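#' Run configuration for the TCSR analysis pipeline
#'
#' Bundles the tunable parameters of the analysis: entropy thresholds for
#' the specific and housekeeping gene-set calls, the nucleosome grid extent,
#' boosting rounds, resampling counts and the control-region offset.
#' A config round-trips losslessly through [write_config()] / [read_config()].
#'
#' @param seed integer seed controlling all stochastic stages.
#' @param h_max overall-entropy ceiling (bits) for the specific call.
#' @param q_max categorical-entropy ceiling (bits) for the specific call.
#' @param h_min_a,h_min_b overall-entropy floors (bits) for the housekeeping
#'   call in the two expression datasets.
#' @param grid_upstream,grid_downstream nucleosome grid extent: number of
#'   nucleosomes upstream / downstream of the TSS (defaults \code{6} and
#'   \code{20}; the alternative \code{-6..+9} extent is \code{downstream = 9}).
#' @param rounds boosting rounds.
#' @param replicates balanced-resampling replicates.
#' @param folds cross-validation folds.
#' @param control_offset distance (bp) of the control anchor upstream of the
#'   TSS. Must exceed the promoter extent.
#' @param tag_anchor how a sequenced-tag interval is reduced to a single
#'   coordinate: \code{"midpoint"} (default) or \code{"five_prime"}.
#'
#' @return An object of class \code{run_config} (a named list).
#' @export
run_config <- function(seed = 1L,
                       h_max = 5.0, q_max = 9.0,
                       h_min_a = 6.2, h_min_b = 8.9,
                       grid_upstream = 6L, grid_downstream = 20L,
                       rounds = 100L, replicates = 100L, folds = 5L,
                       control_offset = 50000L,
                       tag_anchor = c("midpoint", "five_prime")) {
  tag_anchor <- match.arg(tag_anchor)
  cfg <- list(
    seed = as.integer(seed),
    h_max = as.numeric(h_max), q_max = as.numeric(q_max),
    h_min_a = as.numeric(h_min_a), h_min_b = as.numeric(h_min_b),
    grid_upstream = as.integer(grid_upstream),
    grid_downstream = as.integer(grid_downstream),
    rounds = as.integer(rounds),
    replicates = as.integer(replicates),
    folds = as.integer(folds),
    control_offset = as.integer(control_offset),
    tag_anchor = tag_anchor
  )
  counts <- c("rounds", "replicates", "folds", "grid_upstream",
              "grid_downstream", "control_offset")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      stop("config field '", nm, "' must be a positive count", call. = FALSE)
  }
  # promoter extent reaches ~3.1 kb downstream / ~1 kb upstream of the TSS;
  # the control anchor must sit clear of it
  extent <- max(abs(nucleosome_grid(cfg$grid_upstream, cfg$grid_downstream)$end))
  if (cfg$control_offset <= extent)
    stop("control_offset must exceed the promoter extent (", extent, " bp)",
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as a key-value file
#'
#' @param config a [run_config()] object.
#' @param path file path.
#' @return \code{read_config} returns a \code{run_config}; \code{write_config}
#'   returns \code{path} invisibly. The pair is an identity round trip.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lines <- vapply(names(config), function(nm) {
    paste0(nm, "=", as.character(config[[nm]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop("malformed config line ", bad[1], ": '", lines[bad[1]], "'",
         call. = FALSE)
  vals <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, 1L, FUN.VALUE = ""))
  do.call(run_config, vals)
}
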