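test_that("mid-ranks handle ties and conserve the rank sum", {
  expect_equal(rank_with_ties(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rank_with_ties(c(5, 5, 7)), c(1.5, 1.5, 3))
  expect_error(rank_with_ties(c(1, NA)), "non-finite")
  expect_error(rank_with_ties(numeric(0)), "empty")
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    x <- round(rnorm(n), 1)  # rounding forces ties
    r <- rank_with_ties(x)
    expect_equal(sum(r), n * (n + 1) / 2)
    expect_equal(r, rank(x, ties.method = "average"))
  }
})

test_that("Mann-Whitney U: canonical example, degenerate input, tied exact", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_two_sided, 0.1)
  expect_identical(res$method, "exact")

  deg <- mann_whitney_u(c(3, 3, 3), c(3, 3, 3))
  expect_equal(deg$p_two_sided, 1)
  expect_equal(deg$U, 9 / 2)
  expect_identical(deg$method, "degenerate")

  # tied data, forced exact: must equal the enumeration over all 70
  # assignments with mid-ranks
  x <- c(1, 2, 2, 5); y <- c(2, 6, 7, 8)
  res_t <- mann_whitney_u(x, y, mode = "exact")
  expect_equal(res_t$p_two_sided, mw_enumeration_oracle(x, y))
})

test_that("exact U test matches enumeration on random small splits", {
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    vals <- if (i %% 2 == 0) sample(1:6, n1 + n2, replace = TRUE) else
      rnorm(n1 + n2)
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    res <- mann_whitney_u(x, y, mode = "exact")
    expect_equal(res$p_two_sided, mw_enumeration_oracle(x, y),
                 info = sprintf("case %d (n1=%d n2=%d)", i, n1, n2))
    expect_true(res$U >= 0 && res$U <= n1 * n2)
  }
})

test_that("tie-free exact path at cohort sizes matches the reference", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(25); y <- rnorm(8)
    mine <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_identical(mine$method, "exact")
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation agrees with the tie-corrected reference", {
  set.seed(10)
  for (i in 1:10) {
    x <- round(rnorm(20), 1); y <- round(rnorm(15), 1)  # plenty of ties
    mine <- mann_whitney_u(x, y, mode = "normal_approx")
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-10)
  }
})

test_that("null rejection rate of the two-group comparison is ~5%", {
  set.seed(123)
  n_rep <- 2000
  rej <- 0L
  for (i in seq_len(n_rep)) {
    if (mann_whitney_u(rnorm(25), rnorm(8))$p_two_sided < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_rep, 0.04)
  expect_lte(rej / n_rep, 0.06)
})

test_that("Spearman: monotone extremes, tie mid-ranks, rank invariance", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10))$rho, -1)

  # hand-computed Pearson on ranks [1, 2.5, 2.5, 4] vs [1, 2, 3, 4]
  res <- spearman(c(1, 2, 2, 4), c(10, 20, 30, 40))
  expect_equal(res$rho, 4.5 / sqrt(4.5 * 5))

  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    a <- spearman(x, y)
    expect_equal(a$rho, spearman(rank(x), rank(y))$rho)          # rank invariance
    expect_equal(a$rho, spearman(exp(x), y)$rho)                 # monotone transform
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(a$rho, unname(ref$estimate), tolerance = 1e-12)
  }

  cst <- spearman(rep(1, 5), 1:5)
  expect_true(cst$undefined)
  expect_true(is.na(cst$rho))
})

test_that("BH step-up: hand example, ordering, decision equivalence", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(21)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p & q <= 1))
    expect_equal(q, stats::p.adjust(p, "BH"))
    # decision equivalence with the classical step-up rule
    for (alpha in c(0.01, 0.05, 0.1)) {
      m <- length(p)
      ps <- sort(p)
      k <- suppressWarnings(max(which(ps <= alpha * seq_len(m) / m)))
      n_classical <- if (is.finite(k)) k else 0L
      expect_lte(sum(q <= alpha), n_classical)
    }
  }
})

test_that("correlation matrix is symmetric, BH-adjusted and flags constants", {
  set.seed(5)
  df <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  df$d <- df$a + rnorm(20, 0, 0.1)
  cm <- correlation_matrix(df)
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 4))
  expect_true(all(cm$p_adjusted >= cm$p, na.rm = TRUE))
  # two-variable consistency with spearman()
  cm2 <- correlation_matrix(df, c("a", "b"))
  expect_equal(cm2$rho["a", "b"], spearman(df$a, df$b)$rho)
  # constant column flagged undefined, others unaffected
  df$e <- 1
  cm3 <- correlation_matrix(df)
  expect_true(is.na(cm3$rho["a", "e"]))
  expect_false(is.na(cm3$rho["a", "d"]))
})

test_that("marker correlations track the compartment driving OATP", {
  # OATP carried only by myeloid cells; per-case Poisson variation in
  # myeloid density then drives tissue OATP and IBA1 signal jointly
  prof <- default_intensity_profile()
  prof["astrocyte_tumor", "oatp"] <- 0
  prof["stromal", "oatp"] <- 0
  prof["vessel", "oatp"] <- 0
  diffs <- vapply(1:10, function(s) {
    cfg <- generator_config(image_shape = c(128L, 128L),
                            cohort_sizes = c(gbm = 10L, control = 1L),
                            cell_densities = c(myeloid = 1500,
                                               astrocyte_tumor = 1200,
                                               stromal = 900),
                            vessel_params = list(count = 1, width = 5,
                                                 tortuosity = 0.25,
                                                 rim_width = 2),
                            intensity_profile = prof, seed = s)
    gbm <- list()
    for (i in 1:10) {
      cid <- sprintf("gbm_%02d", i)
      gbm[[cid]] <- generate_case_image(cfg, "gbm",
                                        derive_case_seed(s, "gbm", i), cid)
    }
    res <- analyze_cohort(gbm, nuclei = FALSE)
    cm <- res$correlations$gbm
    cm$rho["tissue_mean_integrated_intensity", "iba1_mean_integrated_intensity"] -
      cm$rho["tissue_mean_integrated_intensity", "pdgfrb_mean_integrated_intensity"]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gte(sum(diffs > 0), 7)
})
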