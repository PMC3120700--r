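#' End-to-end TCSR analysis on a synthetic design
#'
#' Runs the full analysis the package implements, from expression to
#' evaluated classifier: (1) simulate the two expression panels and score
#' specificity; (2) call the tissue-specific (positive) and housekeeping
#' (negative) gene sets by their entropy thresholds; (3) simulate the toy
#' genome and per-mark tag tracks; (4) build the requested region's feature
#' table for the called genes; (5) run the balanced-resampling
#' cross-validated evaluation, optionally paired with a control-region
#' baseline and the rank-sum comparison against it.
#'
#' @param design a [simulation_design()].
#' @param region \code{"promoter"} or \code{"body"} featurization.
#' @param replicates,folds,rounds evaluation parameters (see
#'   [replicate_experiment()]).
#' @param control also evaluate a control-region-trained baseline and
#'   compare (default \code{FALSE}).
#' @param seed master seed for the evaluation layer (defaults to the
#'   design's seed).
#' @return List of class \code{tcs_pipeline}: the replicate \code{report},
#'   optional \code{control_report} and \code{comparison}, the called gene
#'   sets, the planted labels, and the feature tables used.
#' @export
run_tcs_pipeline <- function(design = simulation_design(),
                             region = c("promoter", "body"),
                             replicates = 20L, folds = 5L, rounds = 25L,
                             control = FALSE, seed = design$seed) {
  region <- match.arg(region)
  expr <- simulate_expression(design)
  scores_a <- specificity_scores(expr$dataset_a, expr$target_tissue)
  scores_b <- specificity_scores(expr$dataset_b, colnames(expr$dataset_b)[1])
  specific <- call_specific(scores_a)
  housekeeping <- call_housekeeping(scores_a, scores_b)
  if (!length(specific) || !length(housekeeping))
    stop("entropy calls produced an empty gene set", call. = FALSE)
  gen <- simulate_genome(design)
  tracks <- simulate_tags(design, gen$genes, expr$labels)
  used <- gen$genes[gen$genes$id %in% c(specific, housekeeping), ,
                    drop = FALSE]
  ft <- switch(region,
               promoter = promoter_features(used, tracks),
               body = body_features(used, tracks))
  pos <- ft$values[rownames(ft$values) %in% specific, , drop = FALSE]
  neg <- ft$values[rownames(ft$values) %in% housekeeping, , drop = FALSE]
  report <- replicate_experiment(pos, neg, replicates = replicates,
                                 folds = folds, rounds = rounds, seed = seed)
  out <- list(report = report, specific = specific,
              housekeeping = housekeeping, labels = expr$labels,
              features = ft, design = design, region = region)
  if (control) {
    cft <- control_features(used, tracks)
    # control columns renamed to the signal schema so both classifiers see
    # the same feature names
    stopifnot(nrow(cft$values) == nrow(ft$values))
    cvals <- cft$values
    if (region == "promoter") {
      colnames(cvals) <- colnames(ft$values)
      cpos <- cvals[rownames(cvals) %in% specific, , drop = FALSE]
      cneg <- cvals[rownames(cvals) %in% housekeeping, , drop = FALSE]
    } else {
      cpos <- cvals[rownames(cvals) %in% specific, , drop = FALSE]
      cneg <- cvals[rownames(cvals) %in% housekeeping, , drop = FALSE]
    }
    # independently seeded: the signal-vs-control rank-sum test treats the
    # two replicate samples as independent
    out$control_report <- replicate_experiment(
      cpos, cneg, replicates = replicates, folds = folds, rounds = rounds,
      seed = derive_seed(seed, 777L))
    out$comparison <- compare_to_control(report, out$control_report)
  }
  class(out) <- "tcs_pipeline"
  out
}

#' @export
print.tcs_pipeline <- function(x, ...) {
  cat("tcs_pipeline (", x$region, " features): ", length(x$specific),
      " specific vs ", length(x$housekeeping), " housekeeping genes\n",
      sep = "")
  print(x$report)
  if (!is.null(x$comparison))
    cat(sprintf("  signal vs control: p = %.3g %s\n",
                x$comparison$p_value, x$comparison$symbol))
  invisible(x)
}
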