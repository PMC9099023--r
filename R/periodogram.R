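#' Lomb-Scargle periodogram of an activity series
#'
#' Classical normalized Lomb-Scargle: at every test frequency the power is
#' the variance explained by a least-squares sine+cosine fit to the
#' mean-subtracted series, scaled by the total variance,
#' \eqn{P(f) = SSR(f) / (2\hat\sigma^2)}.  Missing bins are simply
#' omitted (the estimator handles gaps natively).  The frequency grid is
#' uniform with `oversampling` times the natural resolution `1/T`.
#'
#' @param series An [activity_series()] (or a tibble with `time_h` and
#'   `counts`).
#' @param period_min_h,period_max_h Period search range in hours.
#' @param oversampling Frequency-grid oversampling factor.
#' @return A `periodogram` tibble: `period_h` (descending), `freq`,
#'   `power`; attributes `n_effective`, `oversampling`, `var_total`.
#' @export
lomb_scargle <- function(series, period_min_h = 16, period_max_h = 35,
                         oversampling = 4) {
  if (period_min_h >= period_max_h) abort("Need period_min_h < period_max_h.")
  t <- series$time_h
  x <- series$counts
  ok <- !is.na(x)
  t <- t[ok]; x <- x[ok]
  span <- max(t) - min(t)
  if (span < 5 * 24)
    abort("Need at least 5 days of data for the periodogram.")
  xc <- x - mean(x)
  s2 <- var(x)
  df <- 1 / (oversampling * span)
  freqs <- seq(1 / period_max_h, 1 / period_min_h, by = df)
  if (s2 == 0) {
    warn("Constant series: all periodogram power is zero.")
    power <- rep(0, length(freqs))
  } else {
    power <- vapply(freqs, function(f) {
      w <- 2 * pi * f
      tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
      ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
      (sum(xc * ct)^2 / sum(ct^2) + sum(xc * st)^2 / sum(st^2)) / (2 * s2)
    }, numeric(1))
  }
  out <- tibble::tibble(period_h = 1 / freqs, freq = freqs, power = power) |>
    dplyr::arrange(dplyr::desc(.data$period_h))
  attr(out, "n_effective") <- length(x)
  attr(out, "time_h") <- t
  attr(out, "oversampling") <- oversampling
  attr(out, "var_total") <- s2
  attr(out, "animal_id") <- attr(series, "animal_id") %||% "series"
  class(out) <- c("periodogram", class(out))
  out
}

#' Significance level for periodogram peak power
#'
#' Analytic mode uses the independent-frequency approximation: with `M`
#' effectively independent frequencies (grid size / oversampling) and
#' exponentially distributed noise power, the level `z` with
#' `P(max power > z) = alpha` is `-log(1 - (1 - alpha)^(1/M))`.
#' Permutation mode shuffles the counts (destroying temporal structure
#' but keeping the marginal distribution) and takes the `1 - alpha`
#' quantile of the permuted maxima.
#'
#' @param periodogram A [lomb_scargle()] result.
#' @param alpha Family-wise false-alarm probability in (0, 1).
#' @param method `"montecarlo"` (default; calibrated on simulated white
#'   noise over the same time and frequency grid, cached per grid
#'   configuration), `"analytic"` (independent-frequency closed form;
#'   anticonservative on oversampled grids), or `"permutation"`
#'   (shuffles the observed counts).
#' @param n_permutations,seed Permutation/Monte-Carlo settings.
#' @param series Required for permutation mode: the series the
#'   periodogram came from.
#' @return Power threshold (scalar).
#' @export
significance_threshold <- function(periodogram, alpha = 0.05,
                                   method = c("montecarlo", "analytic",
                                              "permutation"),
                                   n_permutations = 200, seed = 1,
                                   series = NULL) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1].")
  if (method == "analytic") {
    M <- max(1, round(nrow(periodogram) / attr(periodogram, "oversampling")))
    return(-log(1 - (1 - alpha)^(1 / M)))
  }
  rng <- range(periodogram$period_h)
  os <- attr(periodogram, "oversampling")
  if (method == "montecarlo") {
    n <- attr(periodogram, "n_effective")
    key <- paste(n, round(rng[1], 6), round(rng[2], 6), os, n_permutations,
                 sep = "|")
    maxima <- .threshold_cache[[key]]
    if (is.null(maxima)) {
      tt <- attr(periodogram, "time_h")
      maxima <- withr::with_seed(seed, {
        vapply(seq_len(n_permutations), function(i) {
          noise <- tibble::tibble(time_h = tt, counts = rnorm(length(tt)))
          max(lomb_scargle(noise, rng[1], rng[2], os)$power)
        }, numeric(1))
      })
      .threshold_cache[[key]] <- maxima
    }
    return(as.numeric(quantile(maxima, 1 - alpha, type = 8)))
  }
  if (is.null(series)) abort("Permutation mode needs the original `series`.")
  maxima <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      shuf <- tibble::tibble(time_h = series$time_h,
                             counts = sample(series$counts))
      max(lomb_scargle(shuf, rng[1], rng[2], os)$power)
    }, numeric(1))
  })
  as.numeric(quantile(maxima, 1 - alpha, type = 8))
}

.threshold_cache <- new.env(parent = emptyenv())

# Parabolic refinement of a periodogram maximum on its uniform
# frequency grid; returns the refined frequency.
refine_peak_freq <- function(pg, i) {
  f0 <- pg$freq[i]
  if (i <= 1 || i >= nrow(pg)) return(f0)
  p <- pg$power[c(i - 1, i, i + 1)]
  denom <- p[1] - 2 * p[2] + p[3]
  if (denom >= 0) return(f0)
  dfq <- pg$freq[i + 1] - pg$freq[i]
  f0 + dfq * 0.5 * (p[1] - p[3]) / denom
}

#' Classify free-running behavior and estimate tau
#'
#' Counts genuine periodic components by iterative prewhitening: the
#' Lomb-Scargle periodogram is computed, and while its maximum exceeds
#' the `alpha` significance level the corresponding sinusoid (frequency
#' refined by parabolic interpolation) is recorded and regressed out
#' before re-testing the residual.  This prevents spectral-leakage
#' sidelobes of one strong rhythm from being counted as extra
#' components.  Components closer than `merge_window_h` merge into one.
#' The animal is scored `rhythmic` (exactly one component; tau is its
#' period), `complex` (two or more) or `arrhythmic` (none).
#'
#' @param series An [activity_series()] recorded in constant conditions
#'   (use [series_window()] to drop the entrainment block first).
#' @param alpha Significance level for peak power.
#' @param period_min_h,period_max_h,oversampling Passed to
#'   [lomb_scargle()].
#' @param merge_window_h Components within this distance are one peak.
#' @param max_components Safety cap on extracted components.
#' @return One-row tibble: `animal_id`, `call`, `tau_h`, `n_peaks`,
#'   `peak_periods` (list), `peak_power`, `threshold`.
#' @export
classify_freerun <- function(series, alpha = 0.05, period_min_h = 16,
                             period_max_h = 35, oversampling = 4,
                             merge_window_h = 0.5, max_components = 4) {
  sch <- attr(series, "schedule")
  if (!is.null(sch) && !is_constant_schedule(sch))
    abort("Constant conditions required: the series contains light transitions.")
  work <- tibble::tibble(time_h = series$time_h, counts = series$counts)
  animal <- attr(series, "animal_id") %||% "series"
  peaks <- tibble::tibble(period_h = double(), power = double())
  thr <- NA_real_
  top_power <- NA_real_
  for (k in seq_len(max_components + 1)) {
    pg <- suppressWarnings(
      lomb_scargle(work, period_min_h, period_max_h, oversampling))
    if (k == 1) {
      thr <- significance_threshold(pg, alpha)
      top_power <- max(pg$power)
    }
    i <- which.max(pg$power)
    if (pg$power[i] <= thr || k > max_components) break
    f <- refine_peak_freq(pg, i)
    peaks <- dplyr::add_row(peaks, period_h = 1 / f, power = pg$power[i])
    # prewhiten: remove the fitted waveform at the refined frequency --
    # fundamental plus low harmonics, so non-sinusoidal rhythms do not
    # leave harmonic leakage behind
    ok <- !is.na(work$counts)
    tt <- work$time_h[ok]
    X <- do.call(cbind, lapply(1:3, function(h)
      cbind(cos(2 * pi * h * f * tt), sin(2 * pi * h * f * tt))))
    fit <- lm.fit(cbind(1, X), work$counts[ok])
    work$counts[ok] <- fit$residuals
  }
  # merge components closer than the window (leakage/grid artifacts)
  if (nrow(peaks) > 1) {
    o <- order(peaks$period_h)
    grp <- cumsum(c(1, diff(peaks$period_h[o]) > merge_window_h))
    peaks <- peaks[o, ] |>
      dplyr::mutate(grp = grp) |>
      dplyr::group_by(.data$grp) |>
      dplyr::slice_max(.data$power, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select(-"grp")
  }
  n_pk <- nrow(peaks)
  call <- if (n_pk == 0L) "arrhythmic" else if (n_pk == 1L) "rhythmic" else "complex"
  tibble::tibble(animal_id = animal, call = call,
                 tau_h = if (n_pk == 1L) peaks$period_h[1] else NA_real_,
                 n_peaks = n_pk, peak_periods = list(peaks$period_h),
                 peak_power = top_power, threshold = thr)
}

#' Cohort summary of free-run classifications
#'
#' @param results Tibble of stacked [classify_freerun()] rows.
#' @return Tibble with per-class counts and fractions plus mean/SD tau of
#'   the rhythmic animals.
#' @export
summarize_freerun <- function(results) {
  results |>
    dplyr::summarise(
      n = dplyr::n(),
      n_rhythmic = sum(.data$call == "rhythmic"),
      n_complex = sum(.data$call == "complex"),
      n_arrhythmic = sum(.data$call == "arrhythmic"),
      frac_rhythmic = .data$n_rhythmic / .data$n,
      frac_complex = .data$n_complex / .data$n,
      frac_arrhythmic = .data$n_arrhythmic / .data$n,
      tau_mean_h = mean(.data$tau_h, na.rm = TRUE),
      tau_sd_h = sd(.data$tau_h, na.rm = TRUE)
    )
}
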