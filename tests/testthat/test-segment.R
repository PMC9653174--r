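test_that("Otsu threshold separates bimodal histograms and matches brute force", {
  # two equal masses: threshold below 10, all 50 high pixels foreground
  vals <- c(rep(0, 50), rep(10, 50))
  t1 <- otsu_threshold(vals)
  expect_true(t1 >= 0 && t1 < 10)
  expect_equal(sum(vals > t1), 50)

  # three-mass histogram: only the 100s end up foreground
  vals3 <- c(rep(0, 10), rep(5, 10), rep(100, 10))
  t3 <- otsu_threshold(vals3)
  expect_equal(sum(vals3 > t3), 10)
  expect_equal(t3, otsu_bruteforce_oracle(vals3))

  expect_error(otsu_threshold(rep(7, 100)), "degenerate")

  # histogram-form input agrees with raw values
  h <- cbind(value = c(0, 5, 100), count = c(10, 10, 10))
  expect_equal(otsu_threshold(h), t3)

  # random 8-bit histograms against the brute-force variance maximizer
  set.seed(31)
  for (i in 1:30) {
    v <- sample(0:255, sample(2:40, 1))
    counts <- sample(1:50, length(v), replace = TRUE)
    vals_r <- rep(v, counts)
    expect_equal(otsu_threshold(vals_r), otsu_bruteforce_oracle(vals_r),
                 info = paste("histogram", i))
  }
})

test_that("raising a fixed threshold never increases the foreground", {
  set.seed(4)
  cfg <- small_config(seed = 4L)
  res <- generate_case_image(cfg, "gbm", 44L)
  tissue <- matrix(TRUE, 128, 128)
  prev <- Inf
  for (thr in c(10, 50, 200, 600, 2000)) {
    p <- segmentation_params(threshold_method = "fixed",
                             fixed_thresholds = c(oatp = thr),
                             min_object_area = 1, morphological_cleanup = 0)
    lab <- marker_objects(res$image$channels$oatp, tissue, p, "oatp")
    fg <- sum(lab > 0)
    expect_lte(fg, prev)
    prev <- fg
  }
})

test_that("tissue mask is empty on blank images and tracks object coverage", {
  blank <- structure(list(channels = lapply(oq_channels(), function(ch)
    matrix(20, 96, 96)), case_id = "b", group = "control",
    isoform = "OATP1A2", pixel_size = 0.325, shape = c(96L, 96L)),
    class = "case_image")
  names(blank$channels) <- oq_channels()
  expect_equal(sum(tissue_mask(blank)), 0)

  # dense scene: mask must cover nearly all ground-truth footprints
  cfg <- generator_config(image_shape = c(192L, 192L),
                          cell_counts = c(myeloid = 40L, astrocyte_tumor = 80L,
                                          stromal = 20L),
                          cohort_sizes = c(gbm = 1L, control = 1L), seed = 2L)
  res <- generate_case_image(cfg, "gbm", 17L)
  tm <- tissue_mask(res$image)
  covered <- res$truth$object_labels > 0
  expect_gt(sum(tm & covered) / sum(covered), 0.95)
})

test_that("nuclei detection counts isolated nuclei and splits touching pairs", {
  expect_equal(max(segment_nuclei(matrix(0, 64, 64))), 0)
  expect_error(segment_nuclei(matrix(numeric(0), 0, 0)), "empty")

  # isolated disks: detected count equals ground truth
  cfg <- generator_config(image_shape = c(512L, 512L),
                          cell_counts = c(myeloid = 40L, astrocyte_tumor = 0L,
                                          stromal = 0L),
                          min_spacing = 20,
                          nucleus_radius_frac = 0.8,
                          cohort_sizes = c(gbm = 1L, control = 1L),
                          vessel_params = list(count = 0, width = 5,
                                               tortuosity = 0.25, rim_width = 2),
                          noise = list(background_level = 20, gaussian_sd = 4,
                                       poisson = FALSE),
                          dispersion = 0.1, seed = 13L)
  res <- generate_case_image(cfg, "gbm", 13L)
  n_true <- nrow(res$truth$objects)
  lab <- segment_nuclei(res$image$channels$hoechst,
                        segmentation_params(min_object_area = 10))
  expect_equal(max(lab), n_true)

  # two overlapping disks, centers 1.4 radii apart: watershed finds both
  img <- matrix(0, 96, 96)
  for (ctr in list(c(40, 40), c(40, 54))) {
    d2 <- outer((1:96 - ctr[1])^2, (1:96 - ctr[2])^2, "+")
    img[d2 <= 100] <- 1000
  }
  lab2 <- segment_nuclei(img, segmentation_params(smooth_sigma = 0))
  expect_equal(max(lab2), 2)
  lab1 <- segment_nuclei(img, segmentation_params(smooth_sigma = 0,
                                                  watershed_split = FALSE))
  expect_equal(max(lab1), 1)
})

test_that("marker objects: empty channel, exact footprint, area filter", {
  tissue <- matrix(TRUE, 96, 96)
  flat <- matrix(20, 96, 96)
  p_fb <- segmentation_params(fixed_thresholds = c(oatp = 50))
  expect_equal(max(marker_objects(flat, tissue, p_fb, "oatp")), 0)
  expect_error(marker_objects(flat, tissue, segmentation_params(), "oatp"),
               "degenerate")

  # single zero-noise cell: detected pixel set equals the footprint
  prof <- default_intensity_profile()
  cfg <- zero_noise_config(image_shape = c(96L, 96L),
                           cell_counts = c(myeloid = 1L, astrocyte_tumor = 0L,
                                           stromal = 0L),
                           vessel_params = list(count = 0, width = 5,
                                                tortuosity = 0.25, rim_width = 2),
                           seed = 9L)
  res <- generate_case_image(cfg, "gbm", 9L)
  lab <- marker_objects(res$image$channels$iba1, matrix(TRUE, 96, 96),
                        segmentation_params(morphological_cleanup = 0), "iba1")
  expect_equal(max(lab), 1)
  expect_equal(unname(which(lab > 0)), unname(which(res$truth$object_labels > 0)))

  # area filter removes small objects entirely
  small2 <- matrix(0, 64, 64)
  small2[10:13, 10:14] <- 100   # 20 px
  small2[40:43, 40:44] <- 100   # 20 px
  p50 <- segmentation_params(threshold_method = "fixed",
                             fixed_thresholds = c(x = 50),
                             min_object_area = 50, morphological_cleanup = 0)
  expect_equal(max(marker_objects(small2, matrix(TRUE, 64, 64), p50, "x")), 0)
})

test_that("labeling uses 8-connectivity", {
  m <- matrix(0, 16, 16)
  m[4, 4] <- 100; m[5, 5] <- 100; m[6, 6] <- 100  # diagonal chain
  p <- segmentation_params(threshold_method = "fixed",
                           fixed_thresholds = c(x = 50), min_object_area = 1,
                           morphological_cleanup = 0)
  lab <- marker_objects(m, matrix(TRUE, 16, 16), p, "x")
  expect_equal(max(lab), 1)
})

test_that("myeloid and vessel objects are pixel-disjoint with vessel priority", {
  cfg <- small_config(seed = 19L)
  res <- generate_case_image(cfg, "gbm", 19L)
  seg <- segment_case(res$image)
  expect_equal(sum(seg$myeloid > 0 & seg$vessels > 0), 0)
  # all labeled objects lie within the tissue mask
  expect_true(all(seg$tissue_mask[seg$myeloid > 0]))
  expect_true(all(seg$tissue_mask[seg$vessels > 0]))
  # labels contiguous from 1
  for (lm in list(seg$myeloid, seg$vessels, seg$nuclei)) {
    ids <- sort(unique(lm[lm > 0]))
    if (length(ids) > 0) expect_equal(ids, seq_along(ids))
  }
})

test_that("myeloid recall and precision meet the design target at defaults", {
  cfg <- generator_config(seed = 42L)
  matched <- 0L; n_true <- 0L; fp <- 0L
  for (grp in c("gbm", "control")) {
    for (i in 1:2) {
      res <- generate_case_image(cfg, grp, derive_case_seed(42L, grp, i))
      seg <- segment_case(res$image, nuclei = FALSE)
      gt <- res$truth$objects[res$truth$objects$type == "myeloid", ]
      m <- match_objects(seg$myeloid, gt,
                         min_area = segmentation_params()$min_object_area)
      matched <- matched + m$n_matched_true
      n_true <- n_true + m$n_true
      fp <- fp + m$false_positives
    }
  }
  expect_gte(matched / n_true, 0.95)
  expect_lte(fp / n_true, 0.05)
})
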