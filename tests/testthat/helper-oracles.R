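# Independent oracles used across the suite. These deliberately use a
# different route than the package implementation: brute-force scans,
# full enumeration, and base R reference functions.

# exhaustive two-sided Mann-Whitney p by enumerating every assignment of
# the pooled values to the two groups (mid-ranks via base rank())
mw_enumeration_oracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled, ties.method = "average")
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# brute-force Otsu: scan every candidate split and compute between-class
# variance directly from the two partitions
otsu_bruteforce_oracle <- function(values) {
  v <- sort(unique(values))
  stopifnot(length(v) >= 2)
  best_t <- NA; best_var <- -Inf
  for (t in v[-length(v)]) {
    bg <- values[values <= t]; fg <- values[values > t]
    w0 <- length(bg) / length(values); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (bcv > best_var) { best_var <- bcv; best_t <- t }
  }
  best_t
}

# generator configuration with every stochastic intensity term switched
# off: per-object means then equal the configured profile exactly
zero_noise_config <- function(...) {
  generator_config(dispersion = 0, case_effect_sd = 0, blur_sigma = 0,
                   noise = list(background_level = 20, gaussian_sd = 0,
                                poisson = FALSE),
                   ...)
}

# small, fast config for structural tests
small_config <- function(...) {
  generator_config(image_shape = c(128L, 128L),
                   cohort_sizes = c(gbm = 2L, control = 2L),
                   cell_counts = c(myeloid = 6L, astrocyte_tumor = 10L,
                                   stromal = 3L),
                   vessel_params = list(count = 1, width = 5,
                                        tortuosity = 0.25, rim_width = 2),
                   ...)
}
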