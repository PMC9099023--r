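#' Convert clock hours to radians
#'
#' Maps times on a circular dial of length `period_h` to angles in
#' `[0, 2*pi)`: `2*pi*(t mod period)/period`.
#'
#' @param t_h Hours (vectorized).
#' @param period_h Dial length in hours (default 24).
#' @return Radians in `[0, 2*pi)`.
#' @export
hours_to_radians <- function(t_h, period_h = 24) {
  if (period_h <= 0) abort("`period_h` must be > 0.")
  2 * pi * (t_h %% period_h) / period_h
}

#' Radians back to clock hours
#' @param theta Radians.
#' @param period_h Dial length in hours.
#' @return Hours in `[0, period_h)`.
#' @export
radians_to_hours <- function(theta, period_h = 24) {
  (theta %% (2 * pi)) * period_h / (2 * pi)
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of angles is concentrated around a common
#' direction.  The statistic is `Z = n * rho^2` with `rho` the mean
#' resultant length; the p-value uses the standard series approximation
#' in `1/n`.
#'
#' @param angles_rad Angles in radians (n >= 2).
#' @return One-row tibble: `mean_angle`, `rho`, `z`, `p_value`, `n`.
#' @export
rayleigh_test <- function(angles_rad) {
  angles_rad <- angles_rad[is.finite(angles_rad)]
  n <- length(angles_rad)
  if (n < 2) abort("Rayleigh test needs at least 2 angles.")
  C <- mean(cos(angles_rad)); S <- mean(sin(angles_rad))
  rho <- sqrt(C^2 + S^2)
  z <- n * rho^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  tibble::tibble(mean_angle = atan2(S, C) %% (2 * pi), rho = rho, z = z,
                 p_value = min(max(p, .Machine$double.xmin), 1), n = n)
}

#' Circular mean of angles (radians)
#' @param angles_rad Angles in radians.
#' @return Mean direction in `[0, 2*pi)`.
#' @export
circular_mean <- function(angles_rad) {
  atan2(mean(sin(angles_rad)), mean(cos(angles_rad))) %% (2 * pi)
}

#' Two-sample Watson's U-squared test
#'
#' Nonparametric comparison of two circular samples via the combined
#' ranking formulation (ties handled by evaluating cumulative fractions
#' once per tie block).  The default p-value is a seeded label
#' permutation; an asymptotic mode based on the limiting distribution of
#' U-squared is available for cross-checks.
#'
#' @param sample_a,sample_b Angles in radians (each n >= 4).
#' @param n_permutations Label permutations for the p-value.
#' @param seed Integer seed for the permutation null.
#' @param method `"permutation"` or `"asymptotic"`.
#' @return One-row tibble: `u2`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
watson_u2 <- function(sample_a, sample_b, n_permutations = 10000, seed = 1,
                      method = c("permutation", "asymptotic")) {
  method <- match.arg(method)
  if (length(sample_a) < 4 || length(sample_b) < 4)
    abort("Watson's U2 needs at least 4 angles per sample.")
  a <- sample_a %% (2 * pi); b <- sample_b %% (2 * pi)
  u2 <- cpp_watson_u2(a, b)
  if (length(unique(c(a, b))) == 1L) {
    p <- 1
  } else if (method == "permutation") {
    null <- withr::with_seed(seed, cpp_watson_perm_null(a, b, n_permutations))
    p <- (1 + sum(null >= u2 - 1e-15)) / (n_permutations + 1)
  } else {
    k <- 1:50
    p <- min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * pi^2 * u2))))
  }
  tibble::tibble(u2 = u2, p_value = p, n_a = length(a), n_b = length(b),
                 method = method)
}

#' Grubbs' test for outliers (iterative single-outlier mode)
#'
#' Repeatedly tests the most extreme value against the t-based critical
#' value at `alpha` and removes it while significant.  Assumes
#' approximate normality of the non-outlying data.
#'
#' @param values Numeric vector (n >= 3).
#' @param alpha Significance level per step.
#' @param max_outliers Upper bound on removals.
#' @return Tibble with one row per detected outlier: `index` (position in
#'   the original vector), `value`, `g`, `g_critical`.  Zero rows when no
#'   outlier is found (including the zero-variance case).
#' @export
grubbs_test <- function(values, alpha = 0.05, max_outliers = length(values) - 3) {
  if (length(values) < 3) abort("Grubbs' test needs at least 3 values.")
  out <- tibble::tibble(index = integer(), value = double(),
                        g = double(), g_critical = double())
  live <- seq_along(values)
  repeat {
    x <- values[live]
    n <- length(x)
    if (n < 3 || sd(x) == 0 || nrow(out) >= max_outliers) break
    g <- abs(x - mean(x)) / sd(x)
    i <- which.max(g)
    tcrit <- qt(1 - alpha / (2 * n), n - 2)
    gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (g[i] <= gcrit) break
    out <- dplyr::bind_rows(out, tibble::tibble(
      index = live[i], value = x[i], g = g[i], g_critical = gcrit))
    live <- live[-i]
  }
  out
}
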