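test_that("generator config validation rejects bad parameters", {
  expect_error(generator_config(image_shape = c(32, 512)), ">= 64")
  expect_error(generator_config(oatp_fold = c(myeloid = -1, astrocyte_tumor = 1,
                                              stromal = 1, vessel = 1)), "> 0")
  expect_error(generator_config(cohort_sizes = c(gbm = 0, control = 8)), ">= 1")
  expect_error(generator_config(image_shape = c(64, 64),
                                cell_densities = c(myeloid = 1e7,
                                                   astrocyte_tumor = 1e7,
                                                   stromal = 1e7)),
               "overcrowded")
  expect_error(generate_case_image(small_config(), "plasma", 1), "unknown group")
})

test_that("identical config and seed give bit-identical image and truth", {
  cfg <- small_config(seed = 5L)
  a <- generate_case_image(cfg, "gbm", 12345L, "c1")
  b <- generate_case_image(cfg, "gbm", 12345L, "c1")
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$objects, b$truth$objects)
  expect_identical(a$truth$object_labels, b$truth$object_labels)
  # distinct case seeds produce distinct images
  c2 <- generate_case_image(cfg, "gbm", 54321L, "c2")
  expect_false(identical(a$image$channels$oatp, c2$image$channels$oatp))
})

test_that("empty scene renders flat background with empty ground truth", {
  cfg <- zero_noise_config(image_shape = c(128L, 128L),
                           cell_densities = c(myeloid = 0, astrocyte_tumor = 0,
                                              stromal = 0),
                           vessel_params = list(count = 0, width = 5,
                                                tortuosity = 0.25,
                                                rim_width = 2))
  res <- generate_case_image(cfg, "control", 7L)
  for (ch in oq_channels())
    expect_true(all(res$image$channels[[ch]] == 20), info = ch)
  expect_equal(nrow(res$truth$objects), 0)
  expect_true(all(res$truth$object_labels == 0))
})

test_that("zero-noise per-object means equal configured means exactly", {
  prof <- default_intensity_profile()
  prof["myeloid", "oatp"] <- 500
  cfg <- zero_noise_config(image_shape = c(128L, 128L),
                           cell_counts = c(myeloid = 1L, astrocyte_tumor = 0L,
                                           stromal = 0L),
                           vessel_params = list(count = 0, width = 5,
                                                tortuosity = 0.25,
                                                rim_width = 2),
                           intensity_profile = prof,
                           oatp_fold = 1)
  res <- generate_case_image(cfg, "gbm", 99L)
  expect_equal(nrow(res$truth$objects), 1)
  fp <- res$truth$object_labels == 1
  expect_equal(mean(res$image$channels$oatp[fp]), 500)
  expect_equal(res$truth$objects$true_mean_oatp, 500)
  expect_equal(sum(fp), res$truth$objects$area_px)
})

test_that("ground truth invariants: contiguous ids, consistent footprints, regions partition", {
  cfg <- small_config(seed = 3L,
                      necrosis_params = list(enabled = TRUE, core_fraction = 0.2,
                                             ppn_band_px = 15, pnz_band_px = 15,
                                             ppn_density_boost = 2,
                                             oatp_gradient_scale = 20,
                                             oatp_gradient_amplitude = 2))
  for (grp in c("gbm", "control")) {
    res <- generate_case_image(cfg, grp, 11L)
    obj <- res$truth$objects
    expect_equal(obj$object_id, seq_len(nrow(obj)))
    # rendered objects equal ground-truth rows (conservation)
    expect_equal(sort(unique(res$truth$object_labels[res$truth$object_labels > 0])),
                 obj$object_id)
    areas <- tabulate(res$truth$object_labels[res$truth$object_labels > 0],
                      nbins = nrow(obj))
    expect_equal(areas, obj$area_px)
    # every pixel carries exactly one region code
    expect_true(all(res$truth$regions %in% oq_region_codes()))
  }
})

test_that("cohort layout follows the study design with derived seeds", {
  cfg <- small_config(seed = 2L)
  cohort <- generate_cohort(cfg)
  groups <- vapply(cohort, function(x) x$image$group, character(1))
  expect_equal(sum(groups == "gbm"), 2)
  expect_equal(sum(groups == "control"), 2)
  expect_false(identical(cohort$gbm_01$image$channels$oatp,
                         cohort$gbm_02$image$channels$oatp))
  # default design: 25 GBM vs 8 non-tumor cases
  def <- generator_config()
  expect_equal(unname(def$cohort_sizes[c("gbm", "control")]), c(25, 8))
  # derived seeds are stable and distinct
  s <- derive_case_seed(2L, "gbm", 1L)
  expect_identical(s, derive_case_seed(2L, "gbm", 1L))
  expect_false(s == derive_case_seed(2L, "gbm", 2L))
  expect_false(s == derive_case_seed(2L, "control", 1L))
})

test_that("configured fold is realized exactly at zero noise", {
  base <- zero_noise_config(image_shape = c(160L, 160L),
                            cell_counts = c(myeloid = 8L, astrocyte_tumor = 12L,
                                            stromal = 4L),
                            cohort_sizes = c(gbm = 3L, control = 3L),
                            vessel_params = list(count = 1, width = 5,
                                                 tortuosity = 0.25,
                                                 rim_width = 2),
                            oatp_fold = 2.0, seed = 6L)
  cohort <- generate_cohort(base)
  mean_true_oatp <- function(case)
    mean(case$truth$objects$true_mean_oatp, na.rm = TRUE)
  g <- mean(vapply(cohort[1:3], mean_true_oatp, numeric(1)))
  c0 <- mean(vapply(cohort[4:6], mean_true_oatp, numeric(1)))
  expect_equal(g / c0, 2.0)
})

test_that("peri-necrotic gradient raises OATP near the core", {
  cfg <- small_config(seed = 8L,
                      necrosis_params = list(enabled = TRUE, core_fraction = 0.2,
                                             ppn_band_px = 15, pnz_band_px = 15,
                                             ppn_density_boost = 2,
                                             oatp_gradient_scale = 30,
                                             oatp_gradient_amplitude = 3))
  res <- generate_case_image(cfg, "gbm", 21L)
  rq <- regional_quantify(res$image$channels$oatp, res$truth$regions)
  expect_gt(rq[["PPN"]], rq[["CT"]])
  # control cases carry no necrosis
  res_c <- generate_case_image(cfg, "control", 21L)
  expect_true(all(res_c$truth$regions == oq_region_codes()[["CT"]]))
})

test_that("expression generator: constants, shared factor, layout", {
  genes <- c("SLCO4A1", "VEGFA", "OTHER1", "OTHER2")
  # all loadings zero, no noise: every gene constant across samples
  cfg0 <- expression_config(genes = genes,
                            loadings = setNames(rep(0, 4), genes),
                            noise_sd = 0, samples_per_region = 5L, seed = 1L)
  tab0 <- generate_expression_table(cfg0)
  expect_equal(ncol(tab0$expr), 15)  # 5 samples x 3 regions
  expect_true(all(apply(tab0$expr, 1, function(r) diff(range(r)) == 0)))

  # shared latent factor dominates weak noise
  cfg1 <- expression_config(genes = genes,
                            loadings = setNames(c(1, 1, 0, 0), genes),
                            noise_sd = 0.1, samples_per_region = 67L, seed = 2L)
  tab1 <- generate_expression_table(cfg1)
  expect_gt(spearman(tab1$expr["SLCO4A1", ], tab1$expr["VEGFA", ])$rho, 0.9)
  expect_true(all(tab1$expr > 0))
  expect_error(expression_config(genes = c("A", "A")), "duplicate")
})
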