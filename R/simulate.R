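#' Design of a synthetic TCSR study
#'
#' Describes the planted structure of a synthetic dataset: class sizes,
#' tissue panels for the two expression datasets, marks, the informative
#' (mark, region) pairs with their fold change, the count-noise model, and
#' redundancy groups of marks sharing one latent activation.
#'
#' Defaults mimic the scale of a CD4+ T-cell style study: 400 specific vs
#' 600 housekeeping genes, a 79-tissue and a 600-tissue expression panel,
#' 12 marks of which three are informative (two of them redundant), and
#' overdispersed negative-binomial tag counts.
#'
#' @param n_specific,n_housekeeping gene counts per class.
#' @param n_tissues,n_tissues_b tissue counts of the two expression panels.
#' @param k number of tissues (including the target) in which specific
#'   genes are expressed; must be \code{< n_tissues}.
#' @param n_marks number of HMV tracks (named \code{M01..}).
#' @param informative data.frame with columns \code{mark}, \code{region}
#'   (\code{"promoter"} or \code{"body"}) listing the planted
#'   class-differential pairs. \code{NULL} for a null design.
#' @param f planted fold change (>= 1; 1 is the null).
#' @param base_rate expected tags per nucleosome-sized interval.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed; \code{Inf} approaches Poisson).
#' @param p_active probability that a specific gene activates its redundancy
#'   group's latent amplitude.
#' @param redundancy_groups list of character vectors of marks sharing one
#'   latent Bernoulli amplitude (correlated informative marks).
#' @param cpg_fraction fraction of genes given a CpG island at the TSS.
#' @param multi_exon_fraction fraction of genes with >= 2 exons.
#' @param expression_noise scale of the lognormal expression noise
#'   (default 1; 0 gives exact planted profiles: specific genes silent
#'   outside their tissues, housekeeping exactly uniform).
#' @param seed integer master seed; all outputs are deterministic given it.
#' @return An object of class \code{simulation_design}.
#' @export
simulation_design <- function(n_specific = 400L, n_housekeeping = 600L,
                              n_tissues = 79L, n_tissues_b = 600L, k = 3L,
                              n_marks = 12L,
                              informative = NULL,
                              f = 8, base_rate = 5, dispersion = 4,
                              p_active = 0.9,
                              redundancy_groups = list(c("M01", "M02")),
                              cpg_fraction = 0.5,
                              multi_exon_fraction = 0.9,
                              expression_noise = 1,
                              seed = 1L) {
  if (k >= n_tissues) stop("k must be smaller than n_tissues", call. = FALSE)
  if (base_rate <= 0) stop("base_rate must be positive", call. = FALSE)
  if (f < 1) stop("fold change f must be >= 1", call. = FALSE)
  marks <- sprintf("M%02d", seq_len(n_marks))
  if (missing(informative)) {
    # default planted structure: two redundant promoter marks plus one
    # body mark, clipped to the marks available
    informative <- data.frame(
      mark = c("M01", "M02", "M03"),
      region = c("promoter", "promoter", "body"),
      stringsAsFactors = FALSE)
    informative <- informative[informative$mark %in% marks, , drop = FALSE]
    if (missing(redundancy_groups))
      redundancy_groups <- if (all(c("M01", "M02") %in% marks))
        list(c("M01", "M02")) else list()
  }
  if (!is.null(informative) && nrow(informative) &&
      !all(informative$mark %in% marks))
    stop("informative marks must be among the design's marks", call. = FALSE)
  structure(list(
    n_specific = as.integer(n_specific),
    n_housekeeping = as.integer(n_housekeeping),
    n_tissues = as.integer(n_tissues),
    n_tissues_b = as.integer(n_tissues_b),
    k = as.integer(k), n_marks = as.integer(n_marks), marks = marks,
    informative = informative, f = f, base_rate = base_rate,
    dispersion = dispersion, p_active = p_active,
    redundancy_groups = redundancy_groups,
    cpg_fraction = cpg_fraction,
    multi_exon_fraction = multi_exon_fraction,
    expression_noise = expression_noise,
    seed = as.integer(seed)
  ), class = "simulation_design")
}

gene_ids <- function(design) {
  sprintf("G%04d", seq_len(design$n_specific + design$n_housekeeping))
}

design_labels <- function(design) {
  stats::setNames(rep(c("specific", "housekeeping"),
                      c(design$n_specific, design$n_housekeeping)),
                  gene_ids(design))
}

#' Simulate the two gene-by-tissue expression matrices
#'
#' Specific genes are expressed highly in \code{k} target-adjacent tissues
#' (the target is the first tissue) and at floor level elsewhere, planting
#' low overall and categorical entropy; housekeeping genes get broad
#' lognormal expression in both panels, planting overall entropy above the
#' dual housekeeping thresholds.
#'
#' @param design a [simulation_design()].
#' @return List with \code{dataset_a}, \code{dataset_b} (matrices),
#'   \code{labels} (named character) and \code{target_tissue}.
#' @export
simulate_expression <- function(design) {
  rng <- local_rng(derive_seed(design$seed, 100L))
  on.exit(rng())
  ids <- gene_ids(design)
  labels <- design_labels(design)
  nz <- design$expression_noise
  make_panel <- function(n_tissues, prefix) {
    tissues <- sprintf("%s%03d", prefix, seq_len(n_tissues))
    m <- matrix(1.0, length(ids), n_tissues, dimnames = list(ids, tissues))
    spec <- labels == "specific"
    # specific: high in the first k tissues, background elsewhere
    m[spec, seq_len(design$k)] <-
      300 * exp(stats::rnorm(sum(spec) * design$k, 0, 0.3 * nz))
    m[spec, -seq_len(design$k)] <- if (nz > 0) {
      pmax(1, exp(stats::rnorm(sum(spec) * (n_tissues - design$k), 0,
                               0.2 * nz)))
    } else 0   # noiseless: exact planted profile (silent off-target)
    # housekeeping: broad, mildly noisy lognormal
    m[!spec, ] <- 150 * exp(stats::rnorm(sum(!spec) * n_tissues, 0,
                                         0.15 * nz))
    m
  }
  a <- make_panel(design$n_tissues, "T")
  b <- make_panel(design$n_tissues_b, "S")
  list(dataset_a = a, dataset_b = b, labels = labels,
       target_tissue = colnames(a)[1])
}

#' Simulate a toy genome: gene models and CpG islands
#'
#' Non-overlapping genes with mixed strands on one linear chromosome, each
#' in its own 140-kb slot with enough upstream room for a 50-kb control
#' anchor; a configurable fraction get multiple exons and a CpG island at
#' the TSS.
#'
#' @param design a [simulation_design()].
#' @return List with \code{genes} (a \code{gene_models} data.frame),
#'   \code{islands} (data.frame) and \code{cpg_truth} (named logical).
#' @export
simulate_genome <- function(design) {
  rng <- local_rng(derive_seed(design$seed, 200L))
  on.exit(rng())
  ids <- gene_ids(design)
  n <- length(ids)
  slot <- 140000L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  multi <- stats::runif(n) < design$multi_exon_fraction
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    txstart <- (i - 1L) * slot + 60000L
    n_ex <- if (multi[i]) sample(2:4, 1L) else 1L
    ex_len <- sample(150:600, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L) sample(500:3000, n_ex - 1L, replace = TRUE)
              else integer(0)
    starts <- txstart + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ends <- starts + ex_len - 1L
    exons <- cbind(start = starts, end = ends)
    if (strand[i] == "-")
      exons <- exons[rev(seq_len(n_ex)), , drop = FALSE]
    recs[[i]] <- list(id = ids[i], chrom = "chrS", strand = strand[i],
                      tss = if (strand[i] == "+") txstart else max(ends),
                      txstart = txstart, txend = max(ends), exons = exons)
  }
  genes <- build_gene_models(recs)
  has_island <- stats::runif(n) < design$cpg_fraction
  islands <- data.frame(chrom = rep("chrS", sum(has_island)),
                        start = genes$tss[has_island] - 100L,
                        end = genes$tss[has_island] + 100L)
  genes$cpg_related <- has_island
  list(genes = genes, islands = islands,
       cpg_truth = stats::setNames(has_island, ids))
}

# per-gene latent activation of each redundancy group (shared Bernoulli
# amplitude), drawn once per dataset so grouped marks are correlated
latent_activations <- function(design, labels) {
  rng <- local_rng(derive_seed(design$seed, 299L))
  on.exit(rng())
  lapply(design$redundancy_groups, function(g) {
    a <- as.numeric(stats::runif(length(labels)) < design$p_active)
    a[labels != "specific"] <- 0
    stats::setNames(a, names(labels))
  })
}

#' Simulate per-mark tag tracks with planted class structure
#'
#' Each gene's neighbourhood is partitioned into non-overlapping intervals:
#' the 26 promoter-grid nucleosomes, 150-bp gene-body tiles beyond the
#' grid's downstream end, and the control-anchor grid 50 kb upstream. A tag
#' count is drawn per (gene, mark, interval) from a negative binomial with
#' mean \code{base_rate}, multiplied by the fold change \code{f} when the
#' (mark, region) pair is informative and the gene is specific: promoter
#' effects are planted on the core nucleosomes (-1..+5); body effects on
#' every interval lying inside the gene body (so gene-body marks also show
#' downstream of the TSS in promoter profiles, as real elongation marks
#' do). Marks in a redundancy group share one latent Bernoulli amplitude
#' per gene. Tags are placed uniformly within their interval. Fully
#' deterministic given the design seed.
#'
#' @param design a [simulation_design()].
#' @param genes gene models from [simulate_genome()].
#' @param labels named class labels from [simulate_expression()]; tags are
#'   planted on the genes labelled \code{"specific"}.
#' @return List of [tag_track()] objects, one per mark.
#' @export
simulate_tags <- function(design, genes, labels) {
  grid <- nucleosome_grid()
  core <- grid$index >= -1L & grid$index <= 5L
  labels <- labels[genes$id]
  spec <- labels == "specific"
  plus <- genes$strand == "+"
  n <- nrow(genes)
  acts <- latent_activations(design, labels)
  group_of <- function(mark) {
    hit <- vapply(design$redundancy_groups, function(g) mark %in% g,
                  logical(1))
    if (any(hit)) which(hit)[1] else NA_integer_
  }
  inf_regions <- function(mark) {
    if (is.null(design$informative)) character(0)
    else design$informative$region[design$informative$mark == mark]
  }
  # promoter interval bounds, genes x grid
  p_lo <- outer(genes$tss, grid$start, function(t, s) t + s)
  p_lo[!plus, ] <- outer(genes$tss[!plus], grid$end, function(t, e) t - e)
  p_hi <- outer(genes$tss, grid$end, function(t, e) t + e)
  p_hi[!plus, ] <- outer(genes$tss[!plus], grid$start, function(t, s) t - s)
  # control grid, 50 kb transcript-upstream
  c_anchor <- ifelse(plus, genes$tss - 50000L, genes$tss + 50000L)
  c_lo <- outer(c_anchor, grid$start, function(t, s) t + s)
  c_lo[!plus, ] <- outer(c_anchor[!plus], grid$end, function(t, e) t - e)
  c_hi <- outer(c_anchor, grid$end, function(t, e) t + e)
  c_hi[!plus, ] <- outer(c_anchor[!plus], grid$start, function(t, s) t - s)
  # body tiles beyond the promoter grid's downstream end (rel > 3109), so
  # grid intervals and tiles never overlap
  grid_end <- max(grid$end)
  b_lo <- vector("list", n); b_hi <- vector("list", n)
  for (g in seq_len(n)) {
    if (plus[g]) {
      from <- genes$tss[g] + grid_end + 1L
      if (from > genes$txend[g]) {
        b_lo[[g]] <- numeric(0); b_hi[[g]] <- numeric(0)
      } else {
        s <- seq(from, genes$txend[g], by = 150L)
        b_lo[[g]] <- s
        b_hi[[g]] <- pmin(s + 149L, genes$txend[g])
      }
    } else {
      to <- genes$tss[g] - grid_end - 1L
      if (to < genes$txstart[g]) {
        b_lo[[g]] <- numeric(0); b_hi[[g]] <- numeric(0)
      } else {
        e <- seq(to, genes$txstart[g], by = -150L)
        b_hi[[g]] <- e
        b_lo[[g]] <- pmax(e - 149L, genes$txstart[g])
      }
    }
  }
  n_tiles <- lengths(b_lo)
  # which grid intervals lie inside each gene's body (rel [0, L-1])
  gene_len <- genes$txend - genes$txstart + 1L
  in_body <- outer(gene_len, grid$start,
                   function(L, s) s >= 0) &
    outer(gene_len, grid$end, function(L, e) e <= L - 1L)
  tracks <- vector("list", design$n_marks)
  size <- design$dispersion
  draw_counts <- function(mu) {
    if (is.finite(size)) stats::rnbinom(length(mu), mu = mu, size = size)
    else stats::rpois(length(mu), mu)
  }
  for (m in seq_len(design$n_marks)) {
    mark <- design$marks[m]
    rng <- local_rng(derive_seed(design$seed, 300L + m))
    regions <- inf_regions(mark)
    gi <- group_of(mark)
    amp <- if (!is.na(gi)) acts[[gi]][genes$id] else as.numeric(spec)
    mult <- 1 + (design$f - 1) * amp      # per-gene effect multiplier
    # promoter-grid counts: promoter effects on the core nucleosomes, body
    # effects on grid intervals inside the gene body
    mu_p <- matrix(design$base_rate, n, nrow(grid))
    if ("promoter" %in% regions)
      mu_p[, core] <- mu_p[, core] * mult
    if ("body" %in% regions)
      mu_p <- mu_p * (1 + in_body * (mult - 1))
    cnt_p <- draw_counts(mu_p)
    # tile counts beyond the grid
    mu_b <- rep(design$base_rate, sum(n_tiles))
    if ("body" %in% regions)
      mu_b <- mu_b * rep(mult, n_tiles)
    cnt_b <- draw_counts(mu_b)
    # control counts (never informative)
    cnt_c <- draw_counts(matrix(design$base_rate, n, nrow(grid)))
    lo <- c(as.vector(p_lo), unlist(b_lo), as.vector(c_lo))
    hi <- c(as.vector(p_hi), unlist(b_hi), as.vector(c_hi))
    cnt <- c(as.vector(cnt_p), cnt_b, as.vector(cnt_c))
    total <- sum(cnt)
    pos <- rep(lo, cnt) +
      floor(stats::runif(total) * rep(hi - lo + 1, cnt))
    rng()
    tracks[[m]] <- tag_track(mark, list(chrS = pos))
  }
  tracks
}

#' Write a self-contained synthetic dataset bundle
#'
#' Generates expression matrices, gene models, CpG islands and tag tracks
#' under a design and writes them in the formats the package readers
#' consume (TSV, BED12, BED), together with the truth labels and the
#' design's configuration. The bundle is byte-identical under the same
#' seed.
#'
#' @param design a [simulation_design()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the written \code{paths}, the
#'   \code{labels} and the \code{target_tissue}.
#' @export
make_dataset <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- simulate_expression(design)
  gen <- simulate_genome(design)
  tracks <- simulate_tags(design, gen$genes, expr$labels)
  paths <- list(
    expression_a = file.path(dir, "expression_a.tsv"),
    expression_b = file.path(dir, "expression_b.tsv"),
    genes = file.path(dir, "genes.bed"),
    islands = file.path(dir, "cpg_islands.bed"),
    labels = file.path(dir, "labels.tsv"),
    config = file.path(dir, "config.txt")
  )
  write_expression_matrix(expr$dataset_a, paths$expression_a)
  write_expression_matrix(expr$dataset_b, paths$expression_b)
  write_genes_bed12(gen$genes, paths$genes)
  write_bed_intervals(gen$islands, paths$islands)
  utils::write.table(
    data.frame(gene = names(expr$labels), label = expr$labels),
    paths$labels, sep = "\t", quote = FALSE, row.names = FALSE)
  write_config(run_config(seed = design$seed), paths$config)
  paths$tags <- vapply(tracks, function(tr) {
    p <- file.path(dir, paste0("tags_", tr$mark, ".bed"))
    write_tags_bed(tr, p)
    p
  }, character(1))
  invisible(list(paths = paths, labels = expr$labels,
                 target_tissue = expr$target_tissue))
}
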