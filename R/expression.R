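#' Default gene panel for synthetic niche expression tables
#'
#' The four OATP/SLCO genes, a hypoxia program (CA9, VEGFA, BNIP3, PDK1,
#' NDRG1, ANGPTL4, EGLN3), hypoxia-induced immunogenic/stress genes
#' (CXCL8, IL1R1, TREM1, ATF3), and unloaded filler genes up to `n_genes`.
#'
#' @param n_genes Total panel size (>= 15).
#' @return Character vector of gene names.
#' @export
default_gene_panel <- function(n_genes = 50L) {
  core <- c("SLCO1A2", "SLCO1C1", "SLCO2B1", "SLCO4A1",
            "CA9", "VEGFA", "BNIP3", "PDK1", "NDRG1", "ANGPTL4", "EGLN3",
            "CXCL8", "IL1R1", "TREM1", "ATF3")
  if (n_genes < length(core)) stop("default_gene_panel: n_genes too small")
  c(core, sprintf("NULLGENE%02d", seq_len(n_genes - length(core))))
}

#' Hypoxia-factor loadings for the default panel
#'
#' SLCO4A1 and the hypoxia/immunogenic genes load on the latent hypoxia
#' factor; the other SLCO genes and filler genes do not — encoding the
#' expectation that only SLCO4A1 tracks the hypoxic niche program.
#'
#' @param genes Gene names (default panel).
#' @param loading Loading given to hypoxia-program genes and SLCO4A1.
#' @return Named numeric vector of loadings.
#' @export
default_loadings <- function(genes = default_gene_panel(), loading = 1) {
  l <- stats::setNames(rep(0, length(genes)), genes)
  hyp <- intersect(c("SLCO4A1", "CA9", "VEGFA", "BNIP3", "PDK1", "NDRG1",
                     "ANGPTL4", "EGLN3", "CXCL8", "IL1R1", "TREM1", "ATF3"),
                   genes)
  l[hyp] <- loading
  l
}

#' Configuration for the synthetic region-annotated expression table
#'
#' The generative model is a single latent hypoxia factor: sample s in
#' region r has factor f_s = mu_r + N(0, factor_sd), with mu elevated in
#' the PPN and PNZ niches, and gene g has expression
#' baseline_g * exp(loading_g * f_s + eps), eps ~ N(0, noise_sd). All
#' values are strictly positive by construction.
#'
#' @param genes Gene names (no duplicates).
#' @param loadings Named per-gene loading on the hypoxia factor.
#' @param baseline_mean Per-gene baseline (recycled if scalar), > 0.
#' @param samples_per_region Samples per region, >= 2.
#' @param region_factor_mean Named factor means for CT, PPN, PNZ.
#' @param factor_sd Sd of the per-sample factor around its region mean.
#' @param noise_sd Sd of the per-gene, per-sample log-scale noise.
#' @param seed Integer seed.
#' @return List of class `expression_config`.
#' @export
expression_config <- function(genes = default_gene_panel(),
                              loadings = default_loadings(genes),
                              baseline_mean = 100,
                              samples_per_region = 10L,
                              region_factor_mean = c(CT = 0, PPN = 2, PNZ = 2),
                              factor_sd = 1,
                              noise_sd = 0.3,
                              seed = 1L) {
  if (anyDuplicated(genes)) stop("expression_config: duplicate gene names")
  if (!all(is.finite(loadings))) stop("expression_config: loadings must be finite")
  if (samples_per_region < 2L) stop("expression_config: need >= 2 samples per region")
  baseline <- rep_len(baseline_mean, length(genes))
  if (any(baseline <= 0)) stop("expression_config: baseline means must be > 0")
  loadings <- loadings[genes]
  if (any(is.na(loadings))) stop("expression_config: loadings must cover all genes")
  structure(list(genes = genes, loadings = loadings, baseline = baseline,
                 samples_per_region = as.integer(samples_per_region),
                 region_factor_mean = region_factor_mean,
                 factor_sd = factor_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "expression_config")
}

#' Construct a region-annotated expression table
#'
#' @param expr Non-negative genes x samples numeric matrix with rownames
#'   (genes) and colnames (sample ids).
#' @param regions Character/factor region label per sample (CT/PPN/PNZ).
#' @return List of class `expression_table`: `expr`, `region` (factor),
#'   `genes`.
#' @export
expression_table <- function(expr, regions) {
  if (is.null(rownames(expr))) stop("expression_table: expr needs gene rownames")
  if (anyDuplicated(rownames(expr))) stop("expression_table: duplicate gene names")
  if (length(regions) != ncol(expr))
    stop("expression_table: one region label per sample required")
  if (any(expr < 0)) stop("expression_table: expression must be non-negative")
  structure(list(expr = expr, region = factor(as.character(regions)),
                 genes = rownames(expr)),
            class = "expression_table")
}

#' Generate a synthetic region-annotated expression table
#'
#' Emulates the layout of a niche-resolved GBM expression atlas: genes x
#' samples with each sample annotated CT, PPN or PNZ, where a latent
#' hypoxia factor (elevated in PPN/PNZ) drives the loaded genes.
#'
#' @param config An [expression_config()].
#' @return An [expression_table()].
#' @export
generate_expression_table <- function(config) {
  stopifnot(inherits(config, "expression_config"))
  set.seed(config$seed)
  regions <- names(config$region_factor_mean)
  n_per <- config$samples_per_region
  sample_region <- rep(regions, each = n_per)
  sample_ids <- paste0(sample_region, "_",
                       sprintf("%02d", unlist(lapply(regions, function(r) seq_len(n_per)))))
  f <- config$region_factor_mean[sample_region] +
    rnorm(length(sample_region), 0, config$factor_sd)
  G <- length(config$genes); S <- length(sample_ids)
  eps <- matrix(rnorm(G * S, 0, config$noise_sd), G, S)
  expr <- config$baseline * exp(outer(config$loadings, f) + eps)
  dimnames(expr) <- list(config$genes, sample_ids)
  expression_table(expr, sample_region)
}
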