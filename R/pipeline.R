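#' Pipeline run configuration
#'
#' Bundles the stage configurations behind one object. Exactly one input
#' mode is active: `simulate` renders a synthetic cohort from
#' `generator`, `ingest` reads TIFF cases from `input_dir` (layout:
#' `<case_id>.tif` multi-page or `<case_id>/<case_id>_<channel>.tif`,
#' plus a `cases_manifest.csv` with columns case_id, group, isoform).
#'
#' @param mode "simulate" or "ingest".
#' @param generator A [generator_config()] (simulate mode).
#' @param input_dir Input directory (ingest mode).
#' @param segmentation A [segmentation_params()].
#' @param expression Optional [expression_config()] for the niche stage.
#' @param positivity_q Quantile of control single-cell OATP means used as
#'   the positivity threshold (default 0.99).
#' @param top_n_degs Genes carried into the OATP correlation stage
#'   (default 40).
#' @param outdir Output directory.
#' @param seed Integer seed; overrides the generator seed so one flag
#'   controls every source of randomness.
#' @param log_level "quiet", "info" or "debug".
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"),
                            generator = generator_config(),
                            input_dir = NULL,
                            segmentation = segmentation_params(),
                            expression = NULL,
                            positivity_q = 0.99,
                            top_n_degs = 40L,
                            outdir = "oatpquant_out",
                            seed = NULL,
                            log_level = c("info", "quiet", "debug")) {
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  if (mode == "ingest" && is.null(input_dir))
    stop("pipeline_config: ingest mode needs input_dir")
  if (!is.null(seed)) {
    generator$seed <- as.integer(seed)
    if (!is.null(expression)) expression$seed <- as.integer(seed)
  }
  structure(list(mode = mode, generator = generator, input_dir = input_dir,
                 segmentation = segmentation, expression = expression,
                 positivity_q = positivity_q,
                 top_n_degs = as.integer(top_n_degs),
                 outdir = outdir, log_level = log_level),
            class = "run_config")
}

oq_log <- function(config, level, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[config$log_level]] >= levels[[level]])
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

#' Segment and quantify a cohort of cases
#'
#' The core analysis chain shared by simulated and ingested cohorts:
#' per-case segmentation, case summaries, single-cell measurements,
#' group fold changes for the tissue-wide and per-compartment measures,
#' per-group marker correlation matrices, OATP positivity against the
#' control-percentile threshold, and per-region OATP means where region
#' label maps are available.
#'
#' @param cases Named list of `list(image=, truth=)`; `truth` may be NULL
#'   for ingested data.
#' @param params A [segmentation_params()].
#' @param positivity_q Control quantile for the positivity threshold.
#' @param nuclei Run nuclei detection per case (see [segment_case()]).
#' @return List: `cases` (cohort table), `objects`, `folds`,
#'   `correlations` (per group), `positivity`, `regions`.
#' @export
analyze_cohort <- function(cases, params = segmentation_params(),
                           positivity_q = 0.99, nuclei = TRUE) {
  summaries <- list(); objects <- list(); regions <- list()
  for (case_id in names(cases)) {
    cs <- cases[[case_id]]
    seg <- segment_case(cs$image, params, nuclei = nuclei)
    summaries[[case_id]] <- summarize_case(list(cs$image), list(seg))
    objects[[case_id]] <- case_object_measurements(cs$image, seg)
    if (!is.null(cs$truth) && any(cs$truth$regions != oq_region_codes()[["CT"]])) {
      rq <- regional_quantify(cs$image$channels$oatp, cs$truth$regions)
      regions[[case_id]] <- data.frame(case_id = case_id,
                                       region = names(rq),
                                       mean_oatp = as.numeric(rq),
                                       stringsAsFactors = FALSE)
    }
  }
  cohort <- cohort_table(summaries)
  obj_tab <- do.call(rbind, objects)
  rownames(obj_tab) <- NULL

  measures <- c("tissue_integrated_intensity",
                "tissue_mean_integrated_intensity",
                "percent_area_coverage", "myeloid_mean_oatp",
                "vessel_mean_oatp")
  folds <- list()
  if (all(c("gbm", "control") %in% cohort$group)) {
    for (m in measures) {
      f <- tryCatch(group_fold_change(cohort, m), error = function(e) NULL)
      if (!is.null(f))
        folds[[m]] <- data.frame(measure = m, fold = f$fold,
                                 U = f$test$U, p = f$test$p_two_sided,
                                 method = f$test$method,
                                 stringsAsFactors = FALSE)
    }
  }
  folds <- if (length(folds) > 0) do.call(rbind, folds) else NULL
  if (!is.null(folds)) rownames(folds) <- NULL

  corr_vars <- c("tissue_mean_integrated_intensity",
                 "iba1_mean_integrated_intensity",
                 "gfap_mean_integrated_intensity",
                 "lectin_mean_integrated_intensity",
                 "pdgfrb_mean_integrated_intensity")
  correlations <- list()
  for (grp in intersect(c("gbm", "control"), unique(as.character(cohort$group)))) {
    sub <- cohort[cohort$group == grp, , drop = FALSE]
    if (nrow(sub) >= 4)
      correlations[[grp]] <- correlation_matrix(sub, corr_vars)
  }

  positivity <- NULL
  ctrl_obj <- obj_tab[obj_tab$group == "control", , drop = FALSE]
  gbm_obj <- obj_tab[obj_tab$group == "gbm", , drop = FALSE]
  if (nrow(ctrl_obj) > 0 && nrow(gbm_obj) > 0) {
    positivity <- lapply(c(myeloid = "myeloid", vessel = "vessel"), function(ty) {
      thr <- tryCatch(oatp_positivity_threshold(ctrl_obj, ty, positivity_q),
                      error = function(e) NULL)
      sub <- gbm_obj[gbm_obj$type == ty, , drop = FALSE]
      if (is.null(thr) || nrow(sub) == 0) return(NULL)
      list(threshold = thr, fraction = positive_fraction(sub, thr),
           n_objects = nrow(sub))
    })
    positivity <- positivity[!vapply(positivity, is.null, logical(1))]
  }

  regions <- if (length(regions) > 0) do.call(rbind, regions) else NULL
  if (!is.null(regions)) rownames(regions) <- NULL
  list(cases = cohort, objects = obj_tab, folds = folds,
       correlations = correlations, positivity = positivity,
       regions = regions)
}

read_ingest_cohort <- function(input_dir) {
  manifest_path <- file.path(input_dir, "cases_manifest.csv")
  if (!file.exists(manifest_path))
    stop("run_pipeline: missing cases_manifest.csv in ", input_dir)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  cases <- list()
  for (i in seq_len(nrow(manifest))) {
    cid <- manifest$case_id[i]
    multi <- file.path(input_dir, paste0(cid, ".tif"))
    path <- if (file.exists(multi)) multi else file.path(input_dir, cid)
    if (!file.exists(multi) && !dir.exists(path))
      stop("run_pipeline: case '", cid, "' has no TIFF input")
    img <- read_case_tiff(path, case_id = cid, group = manifest$group[i],
                          isoform = manifest$isoform[i])
    cases[[cid]] <- list(image = img, truth = NULL)
  }
  cases
}

#' Run the full pipeline
#'
#' simulate/ingest -> segment -> quantify -> group statistics -> optional
#' niche expression stage; writes cases.csv, objects.csv, folds.csv,
#' correlations.csv, regions.csv, degs.csv / overlap.json /
#' gene_correlations.csv (when an expression stage is configured) and
#' run_manifest.json into the output directory. Identical configuration
#' and seed give identical CSV contents.
#'
#' @param config A [pipeline_config()].
#' @return The analysis bundle (list), invisibly; side effect: files in
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  res <- tryCatch({
    cases <- if (config$mode == "simulate") {
      oq_log(config, "info", "simulating cohort (",
             config$generator$cohort_sizes[["gbm"]], " gbm + ",
             config$generator$cohort_sizes[["control"]], " control)")
      generate_cohort(config$generator)
    } else {
      oq_log(config, "info", "ingesting cases from ", config$input_dir)
      read_ingest_cohort(config$input_dir)
    }
    stage <- "analysis"
    oq_log(config, "info", "segmenting and quantifying ", length(cases), " cases")
    out <- analyze_cohort(cases, config$segmentation, config$positivity_q)

    stage <- "niche_expression"
    if (!is.null(config$expression)) {
      oq_log(config, "info", "running niche expression stage")
      tab <- generate_expression_table(config$expression)
      deg_ppn <- differential_expression(tab, "PPN")
      deg_pnz <- differential_expression(tab, "PNZ")
      top <- union(top_degs(deg_ppn, config$top_n_degs),
                   top_degs(deg_pnz, config$top_n_degs))
      oatp_genes <- intersect(c("SLCO1A2", "SLCO1C1", "SLCO2B1", "SLCO4A1"),
                              tab$genes)
      out$degs <- rbind(cbind(region = "PPN", deg_ppn),
                        cbind(region = "PNZ", deg_pnz))
      out$overlap <- region_overlap(deg_ppn, deg_pnz)
      if (length(top) >= 1 && length(oatp_genes) >= 1)
        out$gene_correlations <- oatp_gene_correlation(tab, oatp_genes, top)
    }
    out
  }, error = function(e) {
    oq_log(config, "info", "stage '", stage, "' failed: ", conditionMessage(e))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  wr <- function(df, name) {
    if (!is.null(df)) utils::write.csv(df, file.path(config$outdir, name),
                                       row.names = FALSE)
  }
  wr(res$cases, "cases.csv")
  wr(res$objects, "objects.csv")
  wr(res$folds, "folds.csv")
  wr(res$regions, "regions.csv")
  if (length(res$correlations) > 0) {
    long <- do.call(rbind, lapply(names(res$correlations), function(grp) {
      cm <- res$correlations[[grp]]
      df <- write_correlations_long(cm)
      cbind(group = grp, df)
    }))
    utils::write.csv(long, file.path(config$outdir, "correlations.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$degs)) {
    wr(res$degs, "degs.csv")
    jsonlite::write_json(res$overlap, file.path(config$outdir, "overlap.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(res$gene_correlations))
      write_correlations_csv(res$gene_correlations,
                             file.path(config$outdir, "gene_correlations.csv"))
  }

  manifest <- list(
    mode = config$mode,
    seed = config$generator$seed,
    isoform = config$generator$isoform,
    positivity_q = config$positivity_q,
    package_version = as.character(utils::packageVersion("oatpquant")),
    row_counts = list(cases = nrow(res$cases),
                      objects = nrow(res$objects),
                      folds = if (is.null(res$folds)) 0L else nrow(res$folds),
                      regions = if (is.null(res$regions)) 0L else nrow(res$regions)),
    oatp_fold = as.list(config$generator$oatp_fold),
    cohort_sizes = as.list(config$generator$cohort_sizes))
  jsonlite::write_json(manifest, file.path(config$outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  oq_log(config, "info", "wrote outputs to ", config$outdir)
  invisible(res)
}

write_correlations_long <- function(cm) {
  k <- length(cm$variables)
  rows <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    rows[[length(rows) + 1L]] <- data.frame(
      var_a = cm$variables[i], var_b = cm$variables[j],
      rho = cm$rho[i, j], p = cm$p[i, j], p_bh = cm$p_adjusted[i, j],
      n = cm$n[i, j], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build a run configuration from a YAML file
#'
#' The YAML mirrors the constructor arguments: top-level keys `mode`,
#' `outdir`, `seed`, `positivity_q`, `top_n_degs`, `input_dir`, and
#' nested maps `generator`, `segmentation`, `expression` whose entries
#' are passed to [generator_config()], [segmentation_params()] and
#' [expression_config()]. Named YAML maps for vector-valued fields
#' (cohort_sizes, cell_densities, oatp_fold, fixed_thresholds,
#' region_factor_mean, loadings) are converted to named vectors;
#' radius ranges stay lists.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after the file (e.g. `seed`, `outdir`).
#' @return A [pipeline_config()].
#' @export
run_config_from_yaml <- function(path, ...) {
  y <- yaml::read_yaml(path)
  overrides <- list(...)
  for (k in names(overrides)) y[[k]] <- overrides[[k]]
  as_named_vec <- function(x) if (is.list(x)) unlist(x) else x
  gen_args <- y$generator %||% list()
  for (k in c("cohort_sizes", "cell_densities", "cell_counts", "oatp_fold",
              "image_shape"))
    if (!is.null(gen_args[[k]])) gen_args[[k]] <- as_named_vec(gen_args[[k]])
  seg_args <- y$segmentation %||% list()
  if (!is.null(seg_args$fixed_thresholds))
    seg_args$fixed_thresholds <- as_named_vec(seg_args$fixed_thresholds)
  expr_cfg <- NULL
  if (!is.null(y$expression)) {
    ex <- y$expression
    for (k in c("loadings", "region_factor_mean", "baseline_mean"))
      if (!is.null(ex[[k]])) ex[[k]] <- as_named_vec(ex[[k]])
    if (!is.null(ex$genes)) ex$genes <- unlist(ex$genes)
    expr_cfg <- do.call(expression_config, ex)
  }
  pipeline_config(mode = y$mode %||% "simulate",
                  generator = do.call(generator_config, gen_args),
                  input_dir = y$input_dir,
                  segmentation = do.call(segmentation_params, seg_args),
                  expression = expr_cfg,
                  positivity_q = y$positivity_q %||% 0.99,
                  top_n_degs = y$top_n_degs %||% 40L,
                  outdir = y$outdir %||% "oatpquant_out",
                  seed = y$seed,
                  log_level = y$log_level %||% "info")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
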