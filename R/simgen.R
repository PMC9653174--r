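#' @importFrom stats rnorm rpois runif quantile median
NULL

#' Channel names used throughout the package
#'
#' Fixed panel order: Hoechst nuclear counterstain, the OATP isoform under
#' study, IBA1 (pan-myeloid), GFAP (astrocyte/tumor), UEA-1 lectin
#' (endothelial), PDGFRB (stromal/pericyte).
#' @export
oq_channels <- function() c("hoechst", "oatp", "iba1", "gfap", "lectin", "pdgfrb")

#' Region codes for niche label maps
#'
#' Integer codes for the anatomical niches: 0 background (unused in fully
#' simulated tissue), 1 cellular tumor (CT), 2 pseudo-palisading cells
#' around necrosis (PPN), 3 peri-necrotic zone (PNZ), 4 necrotic core.
#' @export
oq_region_codes <- function() {
  c(background = 0L, CT = 1L, PPN = 2L, PNZ = 3L, necrotic_core = 4L)
}

.oq_compartments <- c("myeloid", "astrocyte_tumor", "stromal", "vessel")

#' Default control-tissue intensity profile
#'
#' Per-cell-type mean fluorescence (arbitrary units on a 16-bit-like
#' scale) for each channel in non-tumor tissue. A zero entry means the
#' cell type does not carry that marker and the pixel keeps whatever was
#' rendered underneath. The `nucleus` row is the Hoechst disk painted at
#' the center of every non-vessel cell. The vessel `pdgfrb` entry is the
#' intensity of the pericyte rim around the vessel tube.
#'
#' @return Numeric matrix, rows = cell types + nucleus, cols = channels.
#' @export
default_intensity_profile <- function() {
  ch <- oq_channels()
  prof <- matrix(0, nrow = 5, ncol = length(ch),
                 dimnames = list(c(.oq_compartments, "nucleus"), ch))
  prof["myeloid", c("oatp", "iba1")] <- c(120, 800)
  prof["astrocyte_tumor", c("oatp", "gfap")] <- c(150, 700)
  prof["stromal", c("oatp", "pdgfrb")] <- c(100, 600)
  prof["vessel", c("oatp", "lectin", "pdgfrb")] <- c(200, 900, 500)
  prof["nucleus", "hoechst"] <- 1000
  prof
}

#' Configuration for the synthetic multiplexed IHC generator
#'
#' Builds and validates the full parameter set for simulated case images.
#' Cohort sizes default to the study design this package emulates: 25
#' glioblastoma and 8 non-tumor cases. GBM cases are rendered from the
#' control intensity profile with the per-compartment `oatp_fold`
#' multipliers applied to the OATP channel; passing a single number
#' applies one tissue-level fold to every compartment.
#'
#' Per-case and per-object intensity variation are multiplicative
#' log-normal factors with unit mean, so configured fold changes are
#' preserved in expectation; setting `dispersion`, `case_effect_sd`,
#' `blur_sigma` and the noise terms to zero gives exactly reproducible
#' per-object means (useful for fidelity checks).
#'
#' @param image_shape Integer (rows, cols), each >= 64.
#' @param pixel_size Pixel edge length in micrometers (default 0.325,
#'   a typical 20x slide-scanner sampling).
#' @param cohort_sizes Named counts `c(gbm=, control=)`, each >= 1.
#' @param cell_densities Objects per mm^2 for myeloid, astrocyte_tumor
#'   and stromal cells.
#' @param cell_counts Optional named integer vector fixing the per-case
#'   number of cells per type (overrides Poisson sampling from
#'   densities); useful for controlled fixtures.
#' @param min_spacing Minimum center-to-center distance in px between
#'   cells (rejection-sampled; 0 = unconstrained placement). Lets
#'   controlled fixtures guarantee non-touching cells and nuclei.
#' @param radius_ranges Per-type min/max cell radius in pixels.
#' @param nucleus_radius_frac Nucleus radius as a fraction of cell radius.
#' @param vessel_params List: `count` tubes per image, `width` px,
#'   `tortuosity` (sd, radians, of the per-step direction change),
#'   `rim_width` px of the PDGFRB-positive pericyte rim.
#' @param intensity_profile Control-tissue profile matrix
#'   (see [default_intensity_profile()]).
#' @param dispersion Log-sd of per-object intensity variation.
#' @param case_effect_sd Log-sd of the per-case, per-channel batch factor.
#' @param oatp_fold Named GBM:control OATP multipliers per compartment,
#'   or one number applied to all compartments. Defaults are the
#'   OATP1A2-like profile (myeloid 18, parenchyma 6.1, vessel 6).
#' @param necrosis_params List: `enabled`, `core_fraction` (core radius as
#'   a fraction of the shorter image side), `ppn_band_px`, `pnz_band_px`,
#'   `ppn_density_boost` (cell-density multiplier in the PPN band),
#'   `oatp_gradient_scale` (px; exponential decay length of the
#'   peri-necrotic OATP multiplier), `oatp_gradient_amplitude`.
#' @param noise List: `background_level`, `gaussian_sd`, `poisson` flag.
#' @param blur_sigma Gaussian PSF sigma in pixels applied before noise.
#' @param seed Integer master seed; per-case seeds are derived from it.
#' @param isoform Label recorded in outputs (no effect on rendering).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(image_shape = c(512L, 512L),
                             pixel_size = 0.325,
                             cohort_sizes = c(gbm = 25L, control = 8L),
                             cell_densities = c(myeloid = 1200,
                                                astrocyte_tumor = 2000,
                                                stromal = 600),
                             cell_counts = NULL,
                             min_spacing = 0,
                             radius_ranges = list(myeloid = c(4, 7),
                                                  astrocyte_tumor = c(5, 8),
                                                  stromal = c(4, 6)),
                             nucleus_radius_frac = 0.5,
                             vessel_params = list(count = 4, width = 5,
                                                  tortuosity = 0.25,
                                                  rim_width = 2),
                             intensity_profile = default_intensity_profile(),
                             dispersion = 0.2,
                             case_effect_sd = 0.1,
                             oatp_fold = c(myeloid = 18, astrocyte_tumor = 6.1,
                                           stromal = 6.1, vessel = 6),
                             necrosis_params = list(enabled = FALSE,
                                                    core_fraction = 0.18,
                                                    ppn_band_px = 40,
                                                    pnz_band_px = 40,
                                                    ppn_density_boost = 2,
                                                    oatp_gradient_scale = 60,
                                                    oatp_gradient_amplitude = 2),
                             noise = list(background_level = 20,
                                          gaussian_sd = 8,
                                          poisson = TRUE),
                             blur_sigma = 1,
                             seed = 1L,
                             isoform = "OATP1A2") {
  if (length(oatp_fold) == 1L && is.null(names(oatp_fold))) {
    oatp_fold <- stats::setNames(rep(as.numeric(oatp_fold), 4), .oq_compartments)
  }
  cfg <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
              cohort_sizes = cohort_sizes, cell_densities = cell_densities,
              cell_counts = cell_counts, min_spacing = min_spacing,
              radius_ranges = radius_ranges,
              nucleus_radius_frac = nucleus_radius_frac,
              vessel_params = vessel_params,
              intensity_profile = intensity_profile,
              dispersion = dispersion, case_effect_sd = case_effect_sd,
              oatp_fold = oatp_fold, necrosis_params = necrosis_params,
              noise = noise, blur_sigma = blur_sigma,
              seed = as.integer(seed), isoform = isoform)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 64L))
    stop("generator_config: image_shape must be two values >= 64 px")
  if (cfg$pixel_size <= 0) stop("generator_config: pixel_size must be > 0")
  cs <- cfg$cohort_sizes
  if (!all(c("gbm", "control") %in% names(cs)) || any(cs < 1))
    stop("generator_config: cohort sizes must name gbm and control, each >= 1")
  if (any(cfg$cell_densities < 0)) stop("generator_config: densities must be >= 0")
  if (any(unlist(cfg$radius_ranges) <= 0)) stop("generator_config: radii must be > 0")
  if (any(cfg$intensity_profile < 0)) stop("generator_config: intensities must be >= 0")
  if (cfg$dispersion < 0 || cfg$case_effect_sd < 0)
    stop("generator_config: dispersions must be >= 0")
  if (any(cfg$oatp_fold <= 0)) stop("generator_config: oatp_fold values must be > 0")
  if (!setequal(names(cfg$oatp_fold), .oq_compartments))
    stop("generator_config: oatp_fold must name the four compartments")
  if (cfg$noise$background_level < 0 || cfg$noise$gaussian_sd < 0)
    stop("generator_config: noise levels must be >= 0")
  area_px <- prod(cfg$image_shape)
  area_mm2 <- area_px * (cfg$pixel_size / 1000)^2
  n_expected <- if (!is.null(cfg$cell_counts)) sum(cfg$cell_counts) else
    sum(cfg$cell_densities) * area_mm2
  if (n_expected > area_px / 4) stop("overcrowded configuration")
  invisible(cfg)
}

#' Derive a per-case seed from the master seed
#'
#' A small, documented multiplicative-congruential hash: starting from the
#' master seed, the state is advanced as s <- (s * 69069 + k + 1) mod
#' (2^31 - 1) for k = group code (gbm 1, control 2), case index, and a
#' fixed terminal constant. All intermediates stay below 2^48 so the
#' arithmetic is exact in doubles; the result is a valid 32-bit seed.
#'
#' @param seed Master integer seed.
#' @param group "gbm" or "control".
#' @param case_index 1-based case index within the group.
#' @return Integer seed for the case.
#' @export
derive_case_seed <- function(seed, group, case_index) {
  m <- 2147483647
  gcode <- switch(group, gbm = 1, control = 2,
                  stop("derive_case_seed: unknown group '", group, "'"))
  s <- as.numeric(seed) %% m
  for (k in c(gcode, case_index, 17)) s <- (s * 69069 + k + 1) %% m
  as.integer(s)
}

disk_indices <- function(shape, row, col, radius) {
  r0 <- max(1L, as.integer(floor(row - radius)))
  r1 <- min(shape[1], as.integer(ceiling(row + radius)))
  c0 <- max(1L, as.integer(floor(col - radius)))
  c1 <- min(shape[2], as.integer(ceiling(col + radius)))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  keep <- which(d2 <= radius^2)
  ri <- ((keep - 1L) %% length(rr)) + r0
  ci <- ((keep - 1L) %/% length(rr)) + c0
  (ci - 1L) * shape[1] + ri
}

# unit-mean log-normal multiplier(s)
lognorm_mult <- function(n, sdlog) {
  if (sdlog <= 0) return(rep(1, n))
  exp(rnorm(n, 0, sdlog) - sdlog^2 / 2)
}

build_region_map <- function(shape, center, core_radius, ppn_band, pnz_band) {
  codes <- oq_region_codes()
  d <- sqrt(outer((seq_len(shape[1]) - center[1])^2,
                  (seq_len(shape[2]) - center[2])^2, "+"))
  reg <- matrix(codes[["CT"]], shape[1], shape[2])
  reg[d <= core_radius + ppn_band + pnz_band] <- codes[["PNZ"]]
  reg[d <= core_radius + ppn_band] <- codes[["PPN"]]
  reg[d <= core_radius] <- codes[["necrotic_core"]]
  reg
}

vessel_path_indices <- function(shape, width, tortuosity) {
  # random-walk tube of fixed total path length (twice the longer image
  # side), reflecting at the frame boundary: vessel area per case is
  # then controlled by count and width rather than by how quickly a walk
  # happens to exit the frame
  edge <- sample.int(4L, 1L)
  if (edge == 1L) { pos <- c(1, runif(1, 1, shape[2])); ang <- 0 }        # top, heading down
  if (edge == 2L) { pos <- c(shape[1], runif(1, 1, shape[2])); ang <- pi } # bottom, heading up
  if (edge == 3L) { pos <- c(runif(1, 1, shape[1]), 1); ang <- pi / 2 }    # left, heading right
  if (edge == 4L) { pos <- c(runif(1, 1, shape[1]), shape[2]); ang <- -pi / 2 }
  ang <- ang + rnorm(1, 0, 0.3)
  step <- 1.5
  half <- width / 2
  n_steps <- as.integer(ceiling(2 * max(shape) / step))
  idx <- integer(0)
  for (i in seq_len(n_steps)) {
    idx <- c(idx, disk_indices(shape, pos[1], pos[2], half))
    ang <- ang + rnorm(1, 0, tortuosity)
    nxt <- pos + step * c(cos(ang), sin(ang))
    if (nxt[1] < 1 || nxt[1] > shape[1]) { ang <- pi - ang; nxt <- pos + step * c(cos(ang), sin(ang)) }
    if (nxt[2] < 1 || nxt[2] > shape[2]) { ang <- -ang; nxt <- pos + step * c(cos(ang), sin(ang)) }
    pos <- pmin(pmax(nxt, 1), shape)
  }
  unique(idx)
}

#' Generate one synthetic multiplexed IHC case image with ground truth
#'
#' Renders the six-channel scene for a single case: a uniform background,
#' filled-disk cells (with co-located Hoechst nucleus disks) and
#' random-walk vessel tubes, painted with replace semantics (a later
#' object's intensity overwrites earlier pixels; vessels are drawn last).
#' The noiseless scene is then Gaussian-blurred, shot (Poisson) noise is
#' applied if enabled, Gaussian read noise is added, and values are
#' clipped at zero. Values are kept as floats; quantization to 16 bits
#' happens only on TIFF export.
#'
#' Ground-truth object footprints are the pixels each object owns after
#' overwriting, so per-object means measured over these footprints equal
#' the recorded true means exactly when blur, noise, dispersion and case
#' effects are all zero.
#'
#' For GBM cases with necrosis enabled, an acellular core disk is placed
#' with a PPN band of elevated cell density around it, and each object's
#' OATP mean is multiplied by 1 + A*exp(-d/scale) where d is the centroid
#' distance from the core edge — emulating peri-necrotic OATP4A1
#' enrichment that fades towards the periphery.
#'
#' @param config A [generator_config()].
#' @param group "gbm" or "control".
#' @param case_seed Integer seed for this case (see [derive_case_seed()]).
#' @param case_id Optional case identifier stored in the outputs.
#' @return List with `image` (class `case_image`: named channel matrices
#'   plus metadata) and `truth` (class `ground_truth`: object table,
#'   object label map, region label map, seed).
#' @export
generate_case_image <- function(config, group, case_seed,
                                case_id = paste0(group, "_case")) {
  validate_generator_config(config)
  if (!group %in% c("gbm", "control"))
    stop("generate_case_image: unknown group '", group, "'")
  shape <- config$image_shape
  ch_names <- oq_channels()
  codes <- oq_region_codes()
  set.seed(case_seed)

  prof <- config$intensity_profile
  if (group == "gbm") {
    for (cmp in .oq_compartments)
      prof[cmp, "oatp"] <- prof[cmp, "oatp"] * config$oatp_fold[[cmp]]
  }
  case_eff <- stats::setNames(lognorm_mult(length(ch_names), config$case_effect_sd),
                              ch_names)

  # necrosis geometry (GBM only)
  nec <- config$necrosis_params
  has_necrosis <- group == "gbm" && isTRUE(nec$enabled)
  if (has_necrosis) {
    core_radius <- nec$core_fraction * min(shape)
    margin <- core_radius + nec$ppn_band_px
    center <- c(runif(1, margin, shape[1] - margin),
                runif(1, margin, shape[2] - margin))
    regions <- build_region_map(shape, center, core_radius,
                                nec$ppn_band_px, nec$pnz_band_px)
  } else {
    core_radius <- 0; center <- c(NA_real_, NA_real_)
    regions <- matrix(codes[["CT"]], shape[1], shape[2])
  }

  area_mm2 <- prod(shape) * (config$pixel_size / 1000)^2

  channels <- lapply(ch_names, function(ch)
    matrix(config$noise$background_level, shape[1], shape[2]))
  names(channels) <- ch_names
  owner <- matrix(0L, shape[1], shape[2])

  obj_rows <- list()
  next_id <- 1L

  placed <- matrix(numeric(0), ncol = 2)
  sample_center <- function(radius) {
    # keep the whole footprint inside the frame; reject the necrotic
    # core and (optionally) candidates too close to earlier cells
    for (try in 1:200) {
      p <- c(runif(1, radius + 1, shape[1] - radius),
             runif(1, radius + 1, shape[2] - radius))
      if (has_necrosis && sqrt(sum((p - center)^2)) <= core_radius + radius)
        next
      if (config$min_spacing > 0 && nrow(placed) > 0 &&
          min((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2) <
            config$min_spacing^2)
        next
      break
    }
    placed <<- rbind(placed, p)
    p
  }

  gradient_mult <- function(p) {
    if (!has_necrosis || nec$oatp_gradient_amplitude <= 0) return(1)
    d <- max(0, sqrt(sum((p - center)^2)) - core_radius)
    1 + nec$oatp_gradient_amplitude * exp(-d / nec$oatp_gradient_scale)
  }

  paint_cell <- function(type, p, radius) {
    force(radius)
    idx <- disk_indices(shape, p[1], p[2], radius)
    if (length(idx) == 0) return(invisible(NULL))
    id <- next_id; next_id <<- next_id + 1L
    owner[idx] <<- id
    means <- rep(NA_real_, length(ch_names)); names(means) <- ch_names
    for (ch in ch_names) {
      base <- prof[type, ch]
      if (base <= 0) next
      val <- base * case_eff[[ch]] * lognorm_mult(1, config$dispersion)
      if (ch == "oatp") val <- val * gradient_mult(p)
      channels[[ch]][idx] <<- val
      means[[ch]] <- val
    }
    # co-located nucleus disk on the Hoechst channel (not an owned object)
    if (type != "vessel" && prof["nucleus", "hoechst"] > 0) {
      nidx <- disk_indices(shape, p[1], p[2],
                           max(1, config$nucleus_radius_frac * radius))
      channels$hoechst[nidx] <<- prof["nucleus", "hoechst"] *
        case_eff[["hoechst"]] * lognorm_mult(1, config$dispersion)
    }
    names(means) <- paste0("true_mean_", ch_names)
    obj_rows[[id]] <<- data.frame(object_id = id, type = type,
                                  row = p[1], col = p[2], radius_px = radius,
                                  as.list(means), stringsAsFactors = FALSE)
    invisible(NULL)
  }

  # cells: parenchyma first, then stroma, then myeloid (drawn on top)
  for (type in c("astrocyte_tumor", "stromal", "myeloid")) {
    dens <- config$cell_densities[[type]]
    n_type <- if (!is.null(config$cell_counts)) {
      as.integer(config$cell_counts[[type]])
    } else if (dens > 0) rpois(1, dens * area_mm2) else 0L
    rr <- config$radius_ranges[[type]]
    if (n_type > 0) {
      for (i in seq_len(n_type)) {
        radius <- runif(1, rr[1], rr[2])
        paint_cell(type, sample_center(radius), radius)
      }
    }
    # elevated density in the pseudo-palisading band
    if (has_necrosis && nec$ppn_density_boost > 1 && dens > 0 &&
        is.null(config$cell_counts)) {
      r0 <- core_radius; r1 <- core_radius + nec$ppn_band_px
      band_area_mm2 <- pi * (r1^2 - r0^2) * (config$pixel_size / 1000)^2
      n_extra <- rpois(1, dens * (nec$ppn_density_boost - 1) * band_area_mm2)
      for (i in seq_len(n_extra)) {
        radius <- runif(1, rr[1], rr[2])
        for (try in 1:50) {
          rad_pos <- sqrt(runif(1, r0^2, r1^2))
          theta <- runif(1, 0, 2 * pi)
          p <- center + rad_pos * c(cos(theta), sin(theta))
          if (p[1] > radius && p[1] < shape[1] - radius &&
              p[2] > radius && p[2] < shape[2] - radius) break
        }
        if (p[1] > radius && p[1] < shape[1] - radius &&
            p[2] > radius && p[2] < shape[2] - radius)
          paint_cell(type, p, radius)
      }
    }
  }

  # vessels last: random-walk lectin tubes with a PDGFRB pericyte rim
  vp <- config$vessel_params
  vessel_tube <- matrix(FALSE, shape[1], shape[2])
  if (vp$count > 0) {
    for (v in seq_len(vp$count)) {
      idx <- vessel_path_indices(shape, vp$width, vp$tortuosity)
      if (has_necrosis) {
        ri <- ((idx - 1L) %% shape[1]) + 1L
        ci <- ((idx - 1L) %/% shape[1]) + 1L
        idx <- idx[regions[cbind(ri, ci)] != codes[["necrotic_core"]]]
      }
      if (length(idx) == 0) next
      id <- next_id; next_id <- next_id + 1L
      owner[idx] <- id
      vessel_tube[idx] <- TRUE
      means <- rep(NA_real_, length(ch_names)); names(means) <- ch_names
      ri <- ((idx - 1L) %% shape[1]) + 1L
      ci <- ((idx - 1L) %/% shape[1]) + 1L
      ctr <- c(mean(ri), mean(ci))
      for (ch in c("oatp", "lectin")) {
        base <- prof["vessel", ch]
        if (base <= 0) next
        val <- base * case_eff[[ch]] * lognorm_mult(1, config$dispersion)
        if (ch == "oatp") val <- val * gradient_mult(ctr)
        channels[[ch]][idx] <- val
        means[[ch]] <- val
      }
      names(means) <- paste0("true_mean_", ch_names)
      obj_rows[[id]] <- data.frame(object_id = id, type = "vessel",
                                   row = ctr[1], col = ctr[2],
                                   radius_px = vp$width / 2,
                                   as.list(means), stringsAsFactors = FALSE)
    }
    # pericyte rim: dilation of the tube set, painted on PDGFRB only
    if (any(vessel_tube) && prof["vessel", "pdgfrb"] > 0 && vp$rim_width > 0) {
      brush <- EBImage::makeBrush(2L * as.integer(vp$rim_width) + 1L, "disc")
      dil <- EBImage::imageData(EBImage::dilate(vessel_tube * 1, brush)) > 0
      rim <- dil & !vessel_tube
      channels$pdgfrb[rim] <- prof["vessel", "pdgfrb"] * case_eff[["pdgfrb"]]
    }
  }

  # finalize ground truth from the ownership map (replace semantics)
  truth_df <- if (length(obj_rows) > 0) do.call(rbind, obj_rows) else
    empty_truth_table()
  if (nrow(truth_df) > 0) {
    idx <- which(owner > 0L)
    ids <- owner[idx]
    areas <- tabulate(ids, nbins = max(truth_df$object_id))
    ri <- ((idx - 1L) %% shape[1]) + 1L
    ci <- ((idx - 1L) %/% shape[1]) + 1L
    crow <- tapply(ri, ids, mean)
    ccol <- tapply(ci, ids, mean)
    truth_df$area_px <- areas[truth_df$object_id]
    keep <- truth_df$area_px > 0
    truth_df <- truth_df[keep, , drop = FALSE]
    truth_df$row <- as.numeric(crow[as.character(truth_df$object_id)])
    truth_df$col <- as.numeric(ccol[as.character(truth_df$object_id)])
    # relabel contiguously from 1, preserving draw order
    remap <- integer(max(c(truth_df$object_id, 1L)))
    remap[truth_df$object_id] <- seq_len(nrow(truth_df))
    owner[idx] <- remap[ids]
    truth_df$object_id <- seq_len(nrow(truth_df))
    rownames(truth_df) <- NULL
    truth_df$case_id <- case_id
    truth_df <- truth_df[, c("case_id", "object_id", "type", "row", "col",
                             "radius_px", "area_px",
                             paste0("true_mean_", ch_names))]
  }

  # optics then camera noise: blur -> Poisson shot noise -> Gaussian read
  # noise -> clip at zero
  for (ch in ch_names) {
    img <- channels[[ch]]
    if (config$blur_sigma > 0)
      img <- EBImage::imageData(EBImage::gblur(img, sigma = config$blur_sigma))
    if (isTRUE(config$noise$poisson))
      img <- matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
    if (config$noise$gaussian_sd > 0)
      img <- img + rnorm(length(img), 0, config$noise$gaussian_sd)
    channels[[ch]] <- pmax(img, 0)
  }

  image <- structure(list(channels = channels, case_id = case_id,
                          group = group, isoform = config$isoform,
                          pixel_size = config$pixel_size, shape = shape),
                     class = "case_image")
  truth <- structure(list(objects = truth_df, object_labels = owner,
                          regions = regions, region_codes = codes,
                          seed = case_seed),
                     class = "ground_truth")
  list(image = image, truth = truth)
}

empty_truth_table <- function() {
  ch <- oq_channels()
  df <- data.frame(case_id = character(0), object_id = integer(0),
                   type = character(0), row = numeric(0), col = numeric(0),
                   radius_px = numeric(0), area_px = numeric(0),
                   stringsAsFactors = FALSE)
  for (c0 in ch) df[[paste0("true_mean_", c0)]] <- numeric(0)
  df
}

#' Generate a full two-group cohort of synthetic cases
#'
#' Produces `cohort_sizes["gbm"]` GBM and `cohort_sizes["control"]`
#' control cases. Per-case seeds are derived deterministically from
#' `config$seed` via [derive_case_seed()], so individual cases are
#' reproducible in isolation. GBM cases apply the configured OATP fold
#' multipliers to the control intensity profile.
#'
#' @param config A [generator_config()].
#' @return Named list of `list(image=, truth=)`, one per case; case ids
#'   are `gbm_01..` and `control_01..`.
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  out <- list()
  for (group in c("gbm", "control")) {
    n <- config$cohort_sizes[[group]]
    for (i in seq_len(n)) {
      case_id <- sprintf("%s_%02d", group, i)
      s <- derive_case_seed(config$seed, group, i)
      out[[case_id]] <- generate_case_image(config, group, s, case_id)
    }
  }
  out
}
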