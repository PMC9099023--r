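# Shared builders for the test suite; everything is generated in code.

# Activity series with given per-bin counts repeated over `days` days of a
# 24-h LD schedule (counts vector length = bins per day).
series_from_day <- function(day_counts, days = 5, label = "LD18:6",
                            bin_minutes = 5) {
  sch <- light_schedule(label, span_days = days)
  activity_series(rep(day_counts, days), sch, bin_minutes, "fixture")
}

# Average-day profile with exactly the supplied bin values (no smoothing).
profile_from_values <- function(values, bin_minutes = 5) {
  average_day(series_from_day(values, days = 1, bin_minutes = bin_minutes),
              window_days = 1, sigma_minutes = 0)
}

# von Mises sampler (rejection from the wrapped density peak).
rvonmises <- function(n, mu = 0, kappa = 1) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- runif(n, -pi, pi)
    keep <- runif(n) < exp(kappa * (cos(x) - 1))
    out <- c(out, x[keep])
  }
  (out[seq_len(n)] + mu) %% (2 * pi)
}

# Brute-force Kendall S by pair counting (oracle for the compiled kernel).
kendall_bruteforce <- function(x, y) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
  s
}

wrap_diff_h <- function(a, b) ((a - b + 12) %% 24) - 12
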