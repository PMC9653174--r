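#' Segmentation parameters
#'
#' Explicit, reproducible counterpart of an interactive mask-building
#' workflow: thresholding strategy, nucleus handling and object cleanup.
#'
#' @param threshold_method "otsu" (per channel, per case), "fixed"
#'   (values from `fixed_thresholds`), or "control_percentile" (threshold
#'   = the `control_percentile` quantile of pooled control-cohort pixel
#'   values for the channel; see [control_thresholds()]).
#' @param fixed_thresholds Named per-channel thresholds (a.u.), used by
#'   the "fixed"/"control_percentile" methods and as the fallback when
#'   Otsu is degenerate.
#' @param control_percentile Quantile in (0,1) for the pooled-control
#'   thresholding mode.
#' @param min_object_area Minimum object area in px (objects smaller than
#'   this are discarded). Default 30 px, about 3 um^2 at 0.325 um/px —
#'   excludes nuclear fragments.
#' @param nucleus_radius_range Expected nucleus radii in px (informs the
#'   smoothing scale for nuclei detection).
#' @param watershed_split Split touching nuclei on the distance transform.
#' @param morphological_cleanup Opening radius in px applied to marker
#'   masks before labeling.
#' @param smooth_sigma Gaussian smoothing sigma for nuclei detection.
#' @param vessel_priority Assign pixels positive for both IBA1 and lectin
#'   to vessels (peri-vascular myeloid signal would otherwise be counted
#'   twice).
#' @return List of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed",
                                                     "control_percentile"),
                                fixed_thresholds = NULL,
                                control_percentile = 0.99,
                                min_object_area = 30L,
                                nucleus_radius_range = c(2, 8),
                                watershed_split = TRUE,
                                morphological_cleanup = 1L,
                                smooth_sigma = 1,
                                vessel_priority = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (control_percentile <= 0 || control_percentile >= 1)
    stop("segmentation_params: control_percentile must lie in (0, 1)")
  if (min_object_area < 1) stop("segmentation_params: min_object_area >= 1 required")
  structure(list(threshold_method = threshold_method,
                 fixed_thresholds = fixed_thresholds,
                 control_percentile = control_percentile,
                 min_object_area = as.integer(min_object_area),
                 nucleus_radius_range = nucleus_radius_range,
                 watershed_split = isTRUE(watershed_split),
                 morphological_cleanup = as.integer(morphological_cleanup),
                 smooth_sigma = smooth_sigma,
                 vessel_priority = isTRUE(vessel_priority)),
            class = "segmentation_params")
}

#' Otsu threshold from pixel values or a histogram
#'
#' Returns the threshold maximizing the between-class variance of the
#' background/foreground split; pixels strictly greater than the returned
#' value are foreground. Candidate thresholds are the distinct observed
#' values (splits that leave the foreground empty are not candidates), so
#' the result is exact for any value distribution, not only 8-bit.
#'
#' @param values Numeric pixel values, or a two-column matrix/data.frame
#'   (value, count) histogram.
#' @return The threshold (the largest value assigned to the background
#'   class).
#' @export
otsu_threshold <- function(values) {
  if (is.matrix(values) || is.data.frame(values)) {
    v <- as.numeric(values[, 1]); w <- as.numeric(values[, 2])
    keep <- w > 0
    v <- v[keep]; w <- w[keep]
    ord <- order(v); v <- v[ord]; w <- w[ord]
  } else {
    r <- rle(sort(as.numeric(values), method = "radix"))
    v <- r$values; w <- as.numeric(r$lengths)
  }
  if (length(v) == 0) stop("otsu_threshold: empty histogram")
  if (length(v) == 1L) stop("degenerate histogram")
  n <- sum(w)
  cw <- cumsum(w)                 # background weight for threshold v[k]
  cm <- cumsum(w * v)             # background mass
  total_mean <- cm[length(cm)] / n
  k <- seq_len(length(v) - 1L)    # exclude the empty-foreground split
  w0 <- cw[k] / n
  mu0 <- cm[k] / cw[k]
  w1 <- 1 - w0
  mu1 <- (cm[length(cm)] - cm[k]) / (n - cw[k])
  between <- w0 * w1 * (mu0 - mu1)^2
  v[k[which.max(between)]]
}

#' Estimate the background mode of a channel
#'
#' Most frequent value after binning at unit (intensity-count)
#' resolution — the modal background of a mostly-unstained channel.
#' Coarser bins are only used for ranges beyond 4096 counts.
#' @param channel Numeric matrix.
#' @return Scalar background estimate.
#' @export
background_mode <- function(channel) {
  rng <- range(channel)
  bw <- max(1, (rng[2] - rng[1]) / 4096)
  bins <- round(channel / bw)
  tab <- tabulate(bins - min(bins) + 1L)
  (which.max(tab) + min(bins) - 1L) * bw
}

# background noise sd from the left (below-mode) tail, which object
# signal cannot inflate: for half-normal deviations, sigma =
# median(|d|) / qnorm(0.75)
background_sigma <- function(channel, bg) {
  d <- bg - channel[channel < bg]
  if (length(d) == 0) return(0)
  stats::median(d) / stats::qnorm(0.75)
}

#' Tissue mask from all channels
#'
#' Union of per-channel above-background pixels (background estimated as
#' the per-channel mode, with a tolerance of 4 background noise sds
#' estimated from the below-mode tail), then morphological closing and
#' hole filling. Used to normalize intensity measures to tissue (ROI)
#' area.
#'
#' @param case A `case_image`.
#' @param params [segmentation_params()].
#' @param close_radius Closing radius in px.
#' @return Logical matrix.
#' @export
tissue_mask <- function(case, params = segmentation_params(),
                        close_radius = 5L) {
  stopifnot(inherits(case, "case_image"))
  shape <- dim(case$channels[[1]])
  if (any(shape == 0)) stop("tissue_mask: empty image")
  mask <- matrix(FALSE, shape[1], shape[2])
  for (ch in names(case$channels)) {
    m <- case$channels[[ch]]
    bg <- background_mode(m)
    tol <- 4 * background_sigma(m, bg)
    mask <- mask | (m > bg + tol)
  }
  if (any(mask) && close_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, "disc")
    mask <- EBImage::imageData(EBImage::closing(mask * 1, brush)) > 0
    mask <- EBImage::imageData(EBImage::fillHull(mask * 1)) > 0
  }
  mask
}

# 8-connectivity labeling: EBImage::bwlabel is 4-connected, so
# diagonally adjacent labels are merged with a union-find pass
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  k <- max(lab)
  if (k < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

relabel_contiguous <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) return(lab)
  out <- lab
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

area_filter <- function(lab, min_area) {
  if (max(lab) == 0) return(lab)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- which(areas < min_area)
  if (length(drop) > 0) lab[lab %in% drop] <- 0L
  relabel_contiguous(lab)
}

#' Detect nuclei from the Hoechst channel
#'
#' Gaussian smoothing, Otsu threshold, optional watershed split on the
#' distance transform, and a minimum-area filter. A blank (single-valued)
#' raster yields an empty label map rather than an error.
#'
#' @param hoechst Numeric matrix.
#' @param params [segmentation_params()].
#' @return Integer label map (0 = background, labels contiguous from 1).
#' @export
segment_nuclei <- function(hoechst, params = segmentation_params()) {
  if (length(hoechst) == 0) stop("segment_nuclei: empty raster")
  img <- hoechst
  if (params$smooth_sigma > 0)
    img <- EBImage::imageData(EBImage::gblur(img, sigma = params$smooth_sigma))
  thr <- tryCatch(otsu_threshold(as.vector(img)),
                  error = function(e) NULL)
  if (is.null(thr)) return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  mask <- img > thr
  if (!any(mask)) return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  if (params$watershed_split) {
    dm <- EBImage::distmap(mask * 1)
    lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1))
  } else {
    lab <- label_components8(mask)
  }
  storage.mode(lab) <- "integer"
  area_filter(lab, params$min_object_area)
}

#' Pooled-control channel thresholds
#'
#' Threshold per channel = the configured quantile of all pixel values of
#' that channel pooled across the control cohort. Offered because tumor
#' and control sections are stained in one batch, so control tissue
#' defines the reference intensity distribution.
#'
#' @param control_cases List of `case_image` (the control cohort).
#' @param channels Channel names (default: all).
#' @param q Quantile in (0,1).
#' @return Named numeric thresholds.
#' @export
control_thresholds <- function(control_cases, channels = oq_channels(),
                               q = 0.99) {
  vapply(channels, function(ch) {
    pooled <- unlist(lapply(control_cases, function(cs) as.vector(cs$channels[[ch]])))
    as.numeric(quantile(pooled, q, names = FALSE))
  }, numeric(1))
}

#' Label marker-positive objects in one channel
#'
#' Threshold within the tissue mask (strictly greater than), opening by
#' the cleanup radius, 8-connected components, and minimum-area filter.
#' Used for IBA1+ cells, lectin+ vessels and OATP+ masks alike. With
#' `threshold_method = "otsu"` a degenerate (single-valued) channel falls
#' back to the fixed threshold when one is provided, otherwise errors.
#'
#' @param channel Numeric matrix.
#' @param tissue Logical matrix (tissue mask).
#' @param params [segmentation_params()].
#' @param channel_name Name used to look up `fixed_thresholds`.
#' @return Integer label map.
#' @export
marker_objects <- function(channel, tissue, params = segmentation_params(),
                           channel_name = NULL) {
  if (!all(dim(channel) == dim(tissue)))
    stop("marker_objects: channel and tissue shapes differ")
  fixed <- NULL
  if (!is.null(params$fixed_thresholds)) {
    fixed <- if (!is.null(channel_name) &&
                 channel_name %in% names(params$fixed_thresholds))
      params$fixed_thresholds[[channel_name]]
    else if (is.null(names(params$fixed_thresholds)) &&
             length(params$fixed_thresholds) == 1L)
      params$fixed_thresholds[[1]]
  }
  thr <- switch(params$threshold_method,
    otsu = {
      t0 <- tryCatch(otsu_threshold(as.vector(channel[tissue])),
                     error = function(e) NULL)
      if (is.null(t0)) {
        if (is.null(fixed)) {
          if (!any(tissue)) return(matrix(0L, nrow(channel), ncol(channel)))
          stop("marker_objects: degenerate histogram and no fixed fallback")
        }
        fixed
      } else t0
    },
    fixed = ,
    control_percentile = {
      if (is.null(fixed))
        stop("marker_objects: threshold_method '", params$threshold_method,
             "' needs fixed_thresholds (see control_thresholds())")
      fixed
    })
  mask <- (channel > thr) & tissue
  if (any(mask) && params$morphological_cleanup > 0) {
    brush <- EBImage::makeBrush(2L * params$morphological_cleanup + 1L, "disc")
    mask <- EBImage::imageData(EBImage::opening(mask * 1, brush)) > 0
  }
  lab <- label_components8(mask)
  storage.mode(lab) <- "integer"
  area_filter(lab, params$min_object_area)
}

#' Segment one case into the full mask set
#'
#' Builds the tissue mask, nuclei label map, marker masks for every
#' non-Hoechst channel, IBA1+ myeloid objects and lectin+ vessel objects.
#' When `vessel_priority` is set (default), pixels positive for both IBA1
#' and lectin are assigned to vessels and removed from myeloid objects,
#' so the two object sets are pixel-disjoint.
#'
#' @param case A `case_image`.
#' @param params [segmentation_params()].
#' @param nuclei Detect nuclei (set FALSE to skip the most expensive
#'   stage when only marker objects are needed).
#' @return List of class `segmentation_result`: `tissue_mask`, `nuclei`,
#'   `myeloid`, `vessels`, `marker_masks` (binary rasters per channel).
#' @export
segment_case <- function(case, params = segmentation_params(), nuclei = TRUE) {
  tissue <- tissue_mask(case, params)
  if (nuclei) {
    nuclei <- segment_nuclei(case$channels$hoechst, params)
    nuclei[!tissue] <- 0L
    nuclei <- relabel_contiguous(nuclei)
  } else {
    nuclei <- matrix(0L, nrow(tissue), ncol(tissue))
  }
  marker_masks <- list()
  labs <- list()
  for (ch in setdiff(names(case$channels), "hoechst")) {
    labs[[ch]] <- marker_objects(case$channels[[ch]], tissue, params, ch)
    marker_masks[[ch]] <- labs[[ch]] > 0
  }
  vessels <- labs$lectin
  myeloid <- labs$iba1
  if (params$watershed_split && max(myeloid) > 0) {
    # touching myeloid cells merge into one component; split on the
    # distance transform as for nuclei
    dm <- EBImage::distmap((myeloid > 0) * 1)
    myeloid <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1))
    storage.mode(myeloid) <- "integer"
    myeloid <- area_filter(myeloid, params$min_object_area)
  }
  if (params$vessel_priority) {
    # remove vessel-claimed pixels from already-validated IBA1 objects;
    # the minimum-area rule judges the full IBA1 component as cell
    # evidence, so it is not re-applied to the surviving crescent
    myeloid[vessels > 0] <- 0L
    myeloid <- relabel_contiguous(myeloid)
  }
  structure(list(tissue_mask = tissue, nuclei = nuclei, myeloid = myeloid,
                 vessels = vessels, marker_masks = marker_masks),
            class = "segmentation_result")
}

#' Match detected objects to ground-truth objects
#'
#' A ground-truth object is matched when at least one detected object's
#' centroid lies within one cell radius of its centroid (the drawn
#' `radius_px` when the truth table provides it, else the equivalent
#' radius sqrt(area/pi)). With `min_area > 0`, ground-truth objects whose
#' surviving footprint is below the segmentation's own minimum object
#' area are excluded from the recall denominator: an object almost
#' entirely overwritten by later-drawn objects is by construction not
#' detectable under that area convention.
#'
#' @param detected Integer label map.
#' @param truth_objects Ground-truth object table (rows of one type).
#' @param min_area Detectability floor in px (default 0: all objects).
#'   Recall is computed over objects at or above the floor; detections
#'   are validated against *all* true objects, so a correct detection of
#'   a sub-floor object is not miscounted as a false positive.
#' @return List: `recall`, `n_true`, `n_detected`, `n_matched_true`,
#'   `false_positives`.
#' @export
match_objects <- function(detected, truth_objects, min_area = 0) {
  eligible <- if (min_area > 0) truth_objects$area_px >= min_area else
    rep(TRUE, nrow(truth_objects))
  n_det <- max(detected)
  n_true <- sum(eligible)
  if (nrow(truth_objects) == 0)
    return(list(recall = NA_real_, n_true = 0L, n_detected = n_det,
                n_matched_true = 0L, false_positives = n_det))
  if (n_det == 0)
    return(list(recall = if (n_true > 0) 0 else NA_real_, n_true = n_true,
                n_detected = 0L, n_matched_true = 0L, false_positives = 0L))
  idx <- which(detected > 0)
  ids <- detected[idx]
  nr <- nrow(detected)
  ri <- ((idx - 1L) %% nr) + 1L
  ci <- ((idx - 1L) %/% nr) + 1L
  det_row <- tapply(ri, ids, mean)
  det_col <- tapply(ci, ids, mean)
  radius <- if ("radius_px" %in% names(truth_objects))
    truth_objects$radius_px else sqrt(truth_objects$area_px / pi)
  d2 <- outer(truth_objects$row, det_row, "-")^2 +
    outer(truth_objects$col, det_col, "-")^2
  hit <- d2 <= radius^2
  matched_true <- rowSums(hit[eligible, , drop = FALSE]) >= 1
  det_used <- colSums(hit) >= 1
  list(recall = if (n_true > 0) mean(matched_true) else NA_real_,
       n_true = n_true, n_detected = n_det,
       n_matched_true = sum(matched_true),
       false_positives = sum(!det_used))
}
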