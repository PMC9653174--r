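#' Fold-change recovery experiment
#'
#' The package's core parameter-recovery design: a two-group cohort
#' (default 25 GBM + 8 control, the emulated study layout) is simulated
#' with a configured GBM:control OATP fold, the full
#' segmentation/quantification chain is run blind to the ground truth,
#' and the measured group fold change is compared with the configured
#' one. `compartment = "tissue"` applies the fold to every compartment
#' and reads back the ratio of group mean integrated OATP intensities
#' (channel sum over the OATP-positive mask). The simulated section
#' fills a fixed imaging field, so this ratio equals the ratio of means
#' normalized to ROI area while avoiding the extra sampling noise of an
#' intensity-derived section-area estimate (which matters for ingested
#' slides with off-section glass, not here). `"myeloid"` and `"vessel"`
#' set that compartment's fold (others keep the defaults) and read back
#' the fold of the per-case mean of per-object OATP means in the
#' matching segmented compartment.
#'
#' The control cohort does not depend on the fold, so it is simulated
#' once and shared across all requested fold values.
#'
#' @param folds Numeric vector of configured folds to recover.
#' @param compartment "tissue", "myeloid" or "vessel".
#' @param seed Master seed for the cohort.
#' @param cohort_sizes Named counts `c(gbm=, control=)`.
#' @param image_shape Image size in pixels.
#' @param params [segmentation_params()].
#' @return Data frame: compartment, fold_configured, fold_measured, U, p.
#' @export
fold_recovery_experiment <- function(folds,
                                     compartment = c("tissue", "myeloid",
                                                     "vessel"),
                                     seed = 42L,
                                     cohort_sizes = c(gbm = 25L, control = 8L),
                                     image_shape = c(512L, 512L),
                                     params = segmentation_params()) {
  compartment <- match.arg(compartment)
  measure <- switch(compartment,
                    tissue = "tissue_integrated_intensity",
                    myeloid = "myeloid_mean_oatp",
                    vessel = "vessel_mean_oatp")
  base_cfg <- generator_config(image_shape = image_shape,
                               cohort_sizes = cohort_sizes, seed = seed)
  # control cases are fold-independent: simulate once
  controls <- list()
  for (i in seq_len(cohort_sizes[["control"]])) {
    cid <- sprintf("control_%02d", i)
    controls[[cid]] <- generate_case_image(
      base_cfg, "control", derive_case_seed(seed, "control", i), cid)
  }
  out <- list()
  for (f in folds) {
    of <- base_cfg$oatp_fold
    if (compartment == "tissue") of[] <- f else of[[compartment]] <- f
    cfg <- base_cfg
    cfg$oatp_fold <- of
    gbm <- list()
    for (i in seq_len(cohort_sizes[["gbm"]])) {
      cid <- sprintf("gbm_%02d", i)
      gbm[[cid]] <- generate_case_image(
        cfg, "gbm", derive_case_seed(seed, "gbm", i), cid)
    }
    res <- analyze_cohort(c(gbm, controls), params, nuclei = FALSE)
    fc <- group_fold_change(res$cases, measure)
    out[[length(out) + 1L]] <- data.frame(
      compartment = compartment, fold_configured = f,
      fold_measured = fc$fold, U = fc$test$U, p = fc$test$p_two_sided,
      stringsAsFactors = FALSE)
  }
  res_df <- do.call(rbind, out)
  rownames(res_df) <- NULL
  res_df
}

#' OATP positivity experiment
#'
#' Simulates the default two-group cohort, segments IBA1+ myeloid
#' objects, pools the control cohort's single-cell OATP means to set the
#' positivity threshold (default: control 99th percentile), and reports
#' the percentage of GBM myeloid objects above it.
#'
#' @param seed Master seed.
#' @param q Control quantile for the threshold.
#' @param cohort_sizes Named counts `c(gbm=, control=)`.
#' @param image_shape Image size in pixels.
#' @param params [segmentation_params()].
#' @return List: `percent_positive`, `threshold`, `n_objects`.
#' @export
positivity_experiment <- function(seed = 7L, q = 0.99,
                                  cohort_sizes = c(gbm = 25L, control = 8L),
                                  image_shape = c(512L, 512L),
                                  params = segmentation_params()) {
  cfg <- generator_config(image_shape = image_shape,
                          cohort_sizes = cohort_sizes, seed = seed)
  cases <- generate_cohort(cfg)
  res <- analyze_cohort(cases, params, positivity_q = q, nuclei = FALSE)
  pos <- res$positivity$myeloid
  if (is.null(pos)) stop("positivity_experiment: no myeloid objects detected")
  list(percent_positive = 100 * pos$fraction, threshold = pos$threshold,
       n_objects = pos$n_objects)
}
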