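#' Integrated intensity over a mask
#'
#' Sum of channel values over mask pixels; the mean form divides by the
#' mask pixel count.
#'
#' @param channel Numeric matrix.
#' @param mask Logical matrix of the same shape.
#' @param mean Return the mean instead of the total.
#' @return Scalar intensity (a.u.).
#' @export
integrated_intensity <- function(channel, mask, mean = FALSE) {
  if (!all(dim(channel) == dim(mask)))
    stop("integrated_intensity: shapes differ")
  npix <- sum(mask)
  if (mean && npix == 0) stop("empty ROI")
  total <- sum(channel[mask])
  if (mean) total / npix else total
}

#' Percent area coverage of a marker within tissue
#'
#' 100 * |marker intersect tissue| / |tissue|.
#'
#' @param marker_mask,tissue_mask Logical matrices of equal shape.
#' @return Percentage in [0, 100].
#' @export
percent_area <- function(marker_mask, tissue_mask) {
  if (!all(dim(marker_mask) == dim(tissue_mask)))
    stop("percent_area: shapes differ")
  nt <- sum(tissue_mask)
  if (nt == 0) stop("percent_area: empty tissue mask")
  100 * sum(marker_mask & tissue_mask) / nt
}

#' Per-object mean intensities for one channel
#'
#' One record per label: mean channel intensity over the label's pixels,
#' plus area and centroid.
#'
#' @param channel Numeric matrix.
#' @param objects Integer label map of the same shape.
#' @param case_id,type Identifiers recorded in the output.
#' @return Data frame with columns case_id, object_id, type, area_px,
#'   row, col, mean_intensity. Empty label map gives zero rows.
#' @export
object_mean_intensities <- function(channel, objects, case_id = "case",
                                    type = "object") {
  if (!all(dim(channel) == dim(objects)))
    stop("object_mean_intensities: shapes differ")
  k <- max(objects)
  if (k == 0)
    return(data.frame(case_id = character(0), object_id = integer(0),
                      type = character(0), area_px = numeric(0),
                      row = numeric(0), col = numeric(0),
                      mean_intensity = numeric(0), stringsAsFactors = FALSE))
  idx <- which(objects > 0)
  ids <- objects[idx]
  nr <- nrow(objects)
  ri <- ((idx - 1L) %% nr) + 1L
  ci <- ((idx - 1L) %/% nr) + 1L
  data.frame(case_id = case_id,
             object_id = seq_len(k),
             type = type,
             area_px = as.numeric(tabulate(ids, nbins = k)),
             row = as.numeric(tapply(ri, factor(ids, levels = seq_len(k)), mean)),
             col = as.numeric(tapply(ci, factor(ids, levels = seq_len(k)), mean)),
             mean_intensity = as.numeric(
               tapply(channel[idx], factor(ids, levels = seq_len(k)), mean)),
             stringsAsFactors = FALSE)
}

#' Single-cell measurements for the segmented cell-type compartments
#'
#' Per-object OATP mean intensity within the myeloid (IBA1+) and vessel
#' (lectin+) label maps of one case.
#'
#' @param case A `case_image`.
#' @param seg A `segmentation_result` for that case.
#' @return Data frame of object measurements (myeloid and vessel rows),
#'   with columns as in [object_mean_intensities()] plus `group`.
#' @export
case_object_measurements <- function(case, seg) {
  out <- rbind(
    object_mean_intensities(case$channels$oatp, seg$myeloid,
                            case$case_id, "myeloid"),
    object_mean_intensities(case$channels$oatp, seg$vessels,
                            case$case_id, "vessel"))
  if (nrow(out) > 0) out$group <- case$group
  out
}

#' Fraction of objects positive for a channel
#'
#' Fraction of object measurements with mean intensity strictly greater
#' than the threshold (an object whose mean equals the threshold counts
#' negative).
#'
#' @param measurements Data frame with a `mean_intensity` column.
#' @param threshold Positivity cutoff (a.u.).
#' @return Fraction in [0, 1].
#' @export
positive_fraction <- function(measurements, threshold) {
  if (nrow(measurements) == 0) stop("positive_fraction: no measurements")
  mean(measurements$mean_intensity > threshold)
}

#' OATP positivity threshold from the control cohort
#'
#' The default positivity convention: the 99th percentile of single-cell
#' OATP mean intensities pooled across control-cohort objects of the
#' given type.
#'
#' @param control_measurements Object measurements from control cases.
#' @param type Cell type to pool ("myeloid" or "vessel").
#' @param q Quantile (default 0.99).
#' @return Scalar threshold.
#' @export
oatp_positivity_threshold <- function(control_measurements, type = "myeloid",
                                      q = 0.99) {
  vals <- control_measurements$mean_intensity[control_measurements$type == type]
  if (length(vals) == 0) stop("oatp_positivity_threshold: no control objects of type ", type)
  as.numeric(quantile(vals, q, names = FALSE))
}

measure_one_image <- function(case, seg) {
  oatp <- case$channels$oatp
  tissue <- seg$tissue_mask
  tissue_area <- sum(tissue)
  oatp_mask <- seg$marker_masks$oatp & tissue
  ti <- integrated_intensity(oatp, oatp_mask)
  out <- list(
    tissue_integrated_intensity = ti,
    tissue_mean_integrated_intensity = if (tissue_area > 0) ti / tissue_area else NA_real_,
    percent_area_coverage = if (tissue_area > 0) percent_area(oatp_mask, tissue) else NA_real_,
    n_nuclei = max(seg$nuclei))
  for (type in c("myeloid", "vessel")) {
    lab <- if (type == "myeloid") seg$myeloid else seg$vessels
    om <- object_mean_intensities(oatp, lab, case$case_id, type)
    out[[paste0(type, "_mean_oatp")]] <-
      if (nrow(om) > 0) mean(om$mean_intensity) else NA_real_
    out[[paste0(type, "_n_objects")]] <- nrow(om)
  }
  for (mk in c("iba1", "gfap", "lectin", "pdgfrb")) {
    mmask <- seg$marker_masks[[mk]] & tissue
    out[[paste0(mk, "_mean_integrated_intensity")]] <-
      if (tissue_area > 0) sum(case$channels[[mk]][mmask]) / tissue_area else NA_real_
  }
  out
}

#' Summarize one case into a single row
#'
#' Computes the per-image measures (tissue-wide integrated intensity,
#' mean integrated intensity normalized to tissue area, percent area
#' coverage, per-compartment mean of per-object OATP means, marker
#' tissue intensities) and averages them with equal weight per image —
#' repeated sections of one case enter every downstream statistic as a
#' single value.
#'
#' @param images List of `case_image` for one case (>= 1; one isoform).
#' @param segs Matching list of `segmentation_result`.
#' @return One-row data frame (a CaseSummary).
#' @export
summarize_case <- function(images, segs) {
  if (length(images) < 1) stop("summarize_case: need at least one image")
  if (length(images) != length(segs))
    stop("summarize_case: images and segmentations must pair up")
  isoforms <- unique(vapply(images, function(x) x$isoform, character(1)))
  if (length(isoforms) > 1)
    stop("summarize_case: mixed isoforms within one case panel")
  per_img <- lapply(seq_along(images), function(i)
    measure_one_image(images[[i]], segs[[i]]))
  measures <- names(per_img[[1]])
  avg <- lapply(measures, function(m) {
    vals <- vapply(per_img, function(x) as.numeric(x[[m]]), numeric(1))
    mean(vals, na.rm = FALSE)
  })
  names(avg) <- measures
  data.frame(case_id = images[[1]]$case_id, group = images[[1]]$group,
             isoform = isoforms, as.list(avg), stringsAsFactors = FALSE)
}

#' Build the cohort table from case summaries
#'
#' @param summaries List of one-row data frames from [summarize_case()].
#' @return Data frame, one row per case, `group` as a factor with levels
#'   gbm/control. Duplicate case ids are an error.
#' @export
cohort_table <- function(summaries) {
  tab <- do.call(rbind, summaries)
  if (anyDuplicated(tab$case_id)) stop("cohort_table: duplicate case_ids")
  tab$group <- factor(tab$group, levels = c("gbm", "control"))
  rownames(tab) <- NULL
  tab
}

#' Group fold change with Mann-Whitney test
#'
#' fold = mean(measure | gbm) / mean(measure | control), with a two-sided
#' tie-corrected Mann-Whitney U test on the per-case values. Medians are
#' available via `location = "median"`.
#'
#' @param cohort Cohort table with `group` and the measure column.
#' @param measure Column name.
#' @param location "mean" (default) or "median".
#' @return List: `measure`, `fold`, `test` (an `mw_test`), group means.
#' @export
group_fold_change <- function(cohort, measure, location = c("mean", "median")) {
  location <- match.arg(location)
  if (!measure %in% names(cohort)) stop("group_fold_change: unknown measure ", measure)
  g <- cohort[[measure]][cohort$group == "gbm"]
  c0 <- cohort[[measure]][cohort$group == "control"]
  g <- g[is.finite(g)]; c0 <- c0[is.finite(c0)]
  if (length(g) < 2 || length(c0) < 2)
    stop("group_fold_change: need >= 2 cases per group")
  loc <- if (location == "mean") mean else median
  if (loc(c0) == 0) stop("undefined fold")
  list(measure = measure, fold = loc(g) / loc(c0),
       gbm = loc(g), control = loc(c0),
       test = mann_whitney_u(g, c0))
}

#' Mean intensity per anatomical niche region
#'
#' Mean channel intensity within each of CT, PPN and PNZ; the necrotic
#' core and background codes are excluded. A region absent from the
#' label map is reported as NA (missing), never zero.
#'
#' @param channel Numeric matrix.
#' @param regions Integer region label map (see [oq_region_codes()]).
#' @return Named numeric vector (CT, PPN, PNZ).
#' @export
regional_quantify <- function(channel, regions) {
  if (!all(dim(channel) == dim(regions)))
    stop("regional_quantify: shapes differ")
  codes <- oq_region_codes()
  if (!all(regions %in% codes)) stop("regional_quantify: invalid region codes")
  vapply(c("CT", "PPN", "PNZ"), function(r) {
    sel <- regions == codes[[r]]
    if (!any(sel)) NA_real_ else mean(channel[sel])
  }, numeric(1))
}
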