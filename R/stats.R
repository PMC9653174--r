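#' Mid-ranks with tie averaging
#'
#' Assigns ranks 1..n to a numeric vector; tied values receive the mean of
#' the ranks they jointly cover (mid-ranks). The rank sum is always
#' n(n+1)/2, which is what tie-corrected rank statistics rely on.
#'
#' @param values Numeric vector, all finite.
#' @return Numeric vector of mid-ranks, same length and order as `values`.
#' @export
rank_with_ties <- function(values) {
  if (length(values) == 0L) stop("rank_with_ties: empty input")
  if (!all(is.finite(values))) stop("rank_with_ties: non-finite values")
  ord <- order(values)
  n <- length(values)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && values[ord[j + 1L]] == values[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

#' Two-sample Mann-Whitney U test with tie correction
#'
#' Rank-based two-group comparison. The statistic U is computed for `x`
#' from joint mid-ranks: U = R_x - n1(n1+1)/2. The two-sided p-value is
#' exact where feasible: by full enumeration of the C(n1+n2, n1) rank
#' assignments for small samples (works with ties via mid-ranks), or from
#' the exact tie-free null distribution of U computed by the classical
#' rank-sum counting recursion for larger samples. Otherwise a normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction is used. In `auto` mode the enumeration path is taken when
#' n1+n2 <= 12 and there are no ties, and the counting path whenever the
#' data are tie-free and n1*n2 <= 2000 — so typical per-case cohort
#' comparisons are exact, not approximate.
#'
#' Two-sided exact p doubles the smaller one-tail probability (including
#' the observed value), capped at 1. If every value in both samples is
#' identical, the comparison is degenerate: U = n1*n2/2 and p = 1.
#'
#' @param x,y Numeric samples, each nonempty, all finite.
#' @param mode One of "auto", "exact", "normal_approx".
#' @return A list of class `mw_test`: `U`, `n1`, `n2`, `p_two_sided`,
#'   `method` ("exact", "normal_approx" or "degenerate").
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) < 1L || length(y) < 1L) stop("mann_whitney_u: both samples must be nonempty")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("mann_whitney_u: non-finite values")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank_with_ties(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (length(unique(pooled)) == 1L) {
    return(structure(list(U = n1 * n2 / 2, n1 = n1, n2 = n2,
                          p_two_sided = 1, method = "degenerate"),
                     class = "mw_test"))
  }

  has_ties <- anyDuplicated(pooled) > 0L
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal_approx = FALSE,
                      auto = (n <= 12L && !has_ties) ||
                        (!has_ties && n1 * n2 <= 2000))

  if (use_exact && (n <= 14L || has_ties)) {
    if (has_ties && n > 14L)
      stop("mann_whitney_u: exact mode with ties needs n1+n2 <= 14")
    # enumerate every assignment of n1 of the pooled mid-ranks to group x
    combos <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_lo <- mean(u_all <= U + eps)
    p_hi <- mean(u_all >= U - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else if (use_exact) {
    pmf <- mw_null_pmf(n1, n2)
    u_int <- as.integer(round(U))
    p_lo <- sum(pmf[seq_len(u_int + 1L)])
    p_hi <- sum(pmf[(u_int + 1L):length(pmf)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      return(structure(list(U = U, n1 = n1, n2 = n2, p_two_sided = 1,
                            method = "degenerate"), class = "mw_test"))
    }
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(U = U, n1 = n1, n2 = n2, p_two_sided = p, method = method),
            class = "mw_test")
}

# exact null pmf of U over 0..n1*n2 for tie-free samples: subset-sum
# dynamic programming over the number of ways to pick n1 of the ranks
# 1..n1+n2 with each possible rank sum
mw_null_pmf <- function(n1, n2) {
  N <- n1 + n2
  maxs <- sum((N - n1 + 1L):N)
  ways <- matrix(0, n1 + 1L, maxs + 1L)
  ways[1L, 1L] <- 1
  for (v in seq_len(N)) {
    for (k in min(v, n1):1L) {
      ways[k + 1L, (v + 1L):(maxs + 1L)] <-
        ways[k + 1L, (v + 1L):(maxs + 1L)] + ways[k, 1L:(maxs + 1L - v)]
    }
  }
  counts <- ways[n1 + 1L, ]
  mins <- n1 * (n1 + 1L) / 2           # smallest possible rank sum
  # U = ranksum - mins ranges over 0..n1*n2
  pmf <- counts[(mins + 1L):(maxs + 1L)]
  pmf / sum(pmf)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of the joint mid-ranks of `x` and `y`.
#' The two-sided p-value uses the t approximation with n-2 degrees of
#' freedom; it is flagged approximate for n < 10. Zero rank variance in
#' either variable leaves rho undefined (NA, flagged).
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return List: `rho`, `p`, `n`, `undefined` (logical),
#'   `approximate` (logical, TRUE when n < 10).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("spearman: x and y must be paired")
  n <- length(x)
  if (n < 3L) stop("spearman: need n >= 3")
  rx <- rank_with_ties(x)
  ry <- rank_with_ties(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  vx <- sum(dx^2); vy <- sum(dy^2)
  if (vx == 0 || vy == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n,
                undefined = TRUE, approximate = n < 10L))
  }
  rho <- sum(dx * dy) / sqrt(vx * vy)
  rho <- max(-1, min(1, rho))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  # keep p strictly positive so downstream FDR adjustment stays in (0, 1]
  p <- max(p, .Machine$double.xmin)
  list(rho = rho, p = p, n = n, undefined = FALSE, approximate = n < 10L)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p ascending, computes q_i = p_i * m / i, enforces monotone
#' non-decrease from the largest p downwards, caps at 1, and returns the
#' adjusted values in the original input order.
#'
#' @param p_values Numeric vector, each in (0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("bh_adjust: p-values must lie in (0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  q <- p_values[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Pairwise Spearman correlation matrix with BH adjustment
#'
#' Computes Spearman rho for every variable pair over complete
#' observations, then applies Benjamini-Hochberg adjustment across the
#' upper-triangle p-values. Pairs involving a constant variable are
#' flagged undefined (NA rho/p).
#'
#' @param table Data frame holding the variables as columns.
#' @param variables Character vector of column names (default: all numeric
#'   columns).
#' @return A list of class `correlation_matrix`: `variables`, `rho`, `p`,
#'   `p_adjusted` (symmetric matrices, unit/NA diagonal conventions as
#'   described), and `n` (pairwise complete observations).
#' @export
correlation_matrix <- function(table, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  missing_vars <- setdiff(variables, names(table))
  if (length(missing_vars) > 0)
    stop("correlation_matrix: missing variables: ", paste(missing_vars, collapse = ", "))
  k <- length(variables)
  rho <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  p <- rho; nmat <- matrix(NA_integer_, k, k, dimnames = list(variables, variables))
  diag(rho) <- 1
  for (i in seq_len(k)) nmat[i, i] <- sum(is.finite(table[[variables[i]]]))
  pairs_p <- c(); pairs_idx <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    xi <- table[[variables[i]]]; yj <- table[[variables[j]]]
    ok <- is.finite(xi) & is.finite(yj)
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (sum(ok) < 3) next
    sp <- spearman(xi[ok], yj[ok])
    if (sp$undefined) next
    rho[i, j] <- rho[j, i] <- sp$rho
    p[i, j] <- p[j, i] <- sp$p
    pairs_p <- c(pairs_p, sp$p)
    pairs_idx[[length(pairs_idx) + 1L]] <- c(i, j)
  }
  p_adj <- p
  if (length(pairs_p) > 0) {
    q <- bh_adjust(pairs_p)
    for (m in seq_along(pairs_idx)) {
      ij <- pairs_idx[[m]]
      p_adj[ij[1], ij[2]] <- p_adj[ij[2], ij[1]] <- q[m]
    }
  }
  structure(list(variables = variables, rho = rho, p = p,
                 p_adjusted = p_adj, n = nmat),
            class = "correlation_matrix")
}

#' Write a correlation matrix in long format
#'
#' One row per unordered variable pair: var_a, var_b, rho, p, p_bh, n.
#'
#' @param cm A `correlation_matrix`.
#' @param path Output CSV path.
#' @return The long-format data frame, invisibly.
#' @export
write_correlations_csv <- function(cm, path) {
  k <- length(cm$variables)
  rows <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    rows[[length(rows) + 1L]] <- data.frame(
      var_a = cm$variables[i], var_b = cm$variables[j],
      rho = cm$rho[i, j], p = cm$p[i, j], p_bh = cm$p_adjusted[i, j],
      n = cm$n[i, j], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
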