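#' Smoothed average-day activity profile
#'
#' Folds an activity series modulo 24 h, averages each Zeitgeber-time bin
#' over the window's days, and smooths the profile with a circular
#' Gaussian kernel (the day is periodic, so the kernel wraps; smoothing
#' conserves the profile sum).  Defaults mirror the conventional actogram
#' workflow: a 5- or 10-day window and a 20-min smoothing SD.
#'
#' @param series An [activity_series()].
#' @param window_days Number of complete days to average (the last
#'   `window_days` days of the series).
#' @param sigma_minutes SD of the circular Gaussian smoothing kernel.
#' @return An `avg_day_profile` tibble: `zt` (bin start, hours),
#'   `raw_mean`, `smoothed`; attributes carry the window, kernel and
#'   animal metadata.
#' @export
average_day <- function(series, window_days = 5, sigma_minutes = 20) {
  m <- series_meta(series)
  bins_per_day <- as.integer(24 * 60 / m$bin_minutes)
  n_days <- floor(nrow(series) / bins_per_day)
  if (window_days > n_days)
    abort(sprintf("Series holds %d full day(s); cannot average %d.",
                  n_days, window_days))
  tail_bins <- window_days * bins_per_day
  dat <- dplyr::slice_tail(tibble::as_tibble(series), n = tail_bins)
  grid_idx <- (round(dat$zt * 60 / m$bin_minutes) %% bins_per_day) + 1L
  raw <- tapply(dat$counts, factor(grid_idx, levels = seq_len(bins_per_day)),
                mean, na.rm = TRUE)
  raw <- as.numeric(raw)
  raw[is.nan(raw)] <- 0
  out <- tibble::tibble(
    zt = (seq_len(bins_per_day) - 1L) * m$bin_minutes / 60,
    raw_mean = raw,
    smoothed = smooth_circular(raw, sigma_minutes / m$bin_minutes)
  )
  attr(out, "window_days") <- window_days
  attr(out, "sigma_minutes") <- sigma_minutes
  attr(out, "bin_minutes") <- m$bin_minutes
  attr(out, "animal_id") <- m$animal_id
  attr(out, "genotype") <- m$genotype
  class(out) <- c("avg_day_profile", class(out))
  out
}

# Circular Gaussian smoothing; kernel normalized to sum 1 so the profile
# sum is conserved exactly.
smooth_circular <- function(y, sigma_bins) {
  n <- length(y)
  if (sigma_bins <= 0) return(y)
  half <- min(n %/% 2, max(1L, ceiling(5 * sigma_bins)))
  k <- exp(-((-half:half)^2) / (2 * sigma_bins^2))
  k <- k / sum(k)
  idx <- outer(seq_len(n), -half:half, function(i, o) ((i + o - 1L) %% n) + 1L)
  as.numeric(matrix(y[idx], n) %*% k)
}

# Local maxima on a circular trace with topographic prominence and a
# minimum circular separation (greedy from the highest peak down).
find_peaks_circular <- function(y, min_prominence, min_sep_bins) {
  n <- length(y)
  if (diff(range(y)) == 0) return(integer())
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1))
  cand <- which(y > y[prv] & y >= y[nxt])
  if (length(cand) == 0L) return(integer())
  prominence <- vapply(cand, function(i) {
    saddle <- -Inf
    for (step in list(nxt, prv)) {
      j <- step[i]; low <- y[j]
      while (j != i && y[j] <= y[i]) {
        low <- min(low, y[j]); j <- step[j]
      }
      if (j == i) low <- min(y)    # wrapped: global max; saddle = global min
      saddle <- max(saddle, low)
    }
    y[i] - saddle
  }, numeric(1))
  keep <- cand[prominence >= min_prominence]
  if (length(keep) == 0L) return(integer())
  keep <- keep[order(y[keep], decreasing = TRUE)]
  acc <- integer()
  for (i in keep) {
    d <- abs(i - acc); d <- pmin(d, n - d)
    if (all(d >= min_sep_bins)) acc <- c(acc, i)
  }
  sort(acc)
}

#' Score an animal rhythmic or arrhythmic under the light--dark cycle
#'
#' An animal is `rhythmic_LD` when every analyzed day shows exactly one
#' activity peak in the 24-h period; several irregular peaks (or none) on
#' any day score it `arrhythmic_LD`.  Peaks are circular local maxima of
#' each day's smoothed trace with prominence at least `prominence_frac`
#' of that day's range and circular separation at least
#' `min_separation_hours`.  With `mode = "averaged"` the multi-day
#' averaged profile is scored instead of each day.
#'
#' @inheritParams average_day
#' @param day_sigma_minutes Smoothing SD for the single-day traces being
#'   peak-counted.  Wider than the profile smoothing because one day of
#'   Poisson counts is far noisier than a multi-day average; 60 min
#'   suppresses spurious single-day noise peaks without merging genuine
#'   bimodality (peaks >= 4 h apart).
#' @param prominence_frac Prominence threshold as a fraction of the daily
#'   smoothed range.
#' @param min_separation_hours Minimum circular distance between peaks.
#' @param mode `"per_day"` (score each day) or `"averaged"`.
#' @return A one-row tibble: `animal_id`, `genotype`, `call`
#'   (`"rhythmic_LD"`, `"arrhythmic_LD"` or `"inactive"`),
#'   `per_day_peaks` (list of per-day peak counts), `peak_zt` (circular
#'   mean peak time when rhythmic).
#' @export
classify_ld <- function(series, window_days = 5, sigma_minutes = 20,
                        day_sigma_minutes = 60,
                        prominence_frac = 0.25, min_separation_hours = 4,
                        mode = c("per_day", "averaged")) {
  mode <- match.arg(mode)
  m <- series_meta(series)
  bins_per_day <- as.integer(24 * 60 / m$bin_minutes)
  n_days <- floor(nrow(series) / bins_per_day)
  if (window_days > n_days)
    abort(sprintf("Need %d full days, series has %d.", window_days, n_days))
  sep_bins <- min_separation_hours * 60 / m$bin_minutes
  dat <- dplyr::slice_tail(tibble::as_tibble(series), n = window_days * bins_per_day)
  day_of <- rep(seq_len(window_days), each = bins_per_day)

  day_traces <- if (mode == "per_day") {
    split(dat$counts, day_of)
  } else {
    prof <- average_day(series, window_days, sigma_minutes)
    list(prof$raw_mean)
  }
  if (any(vapply(day_traces, function(v) all(v == 0, na.rm = TRUE), logical(1)))) {
    inform(sprintf("Animal %s inactive (an all-zero day); excluded from LD scoring.",
                   m$animal_id))
    return(tibble::tibble(animal_id = m$animal_id, genotype = m$genotype,
                          call = "inactive", per_day_peaks = list(integer()),
                          peak_zt = NA_real_))
  }
  zt_grid <- dat$zt[seq_len(bins_per_day)]
  trace_sigma <- if (mode == "per_day") day_sigma_minutes else sigma_minutes
  peaks <- purrr::map(day_traces, function(v) {
    v[is.na(v)] <- 0
    sm <- smooth_circular(v, trace_sigma / m$bin_minutes)
    find_peaks_circular(sm, prominence_frac * diff(range(sm)), sep_bins)
  })
  counts <- vapply(peaks, length, integer(1))
  rhythmic <- all(counts == 1L)
  peak_zt <- if (rhythmic) {
    ang <- 2 * pi * zt_grid[vapply(peaks, `[`, integer(1), 1)] / 24
    (atan2(mean(sin(ang)), mean(cos(ang))) %% (2 * pi)) * 24 / (2 * pi)
  } else NA_real_
  tibble::tibble(animal_id = m$animal_id, genotype = m$genotype,
                 call = if (rhythmic) "rhythmic_LD" else "arrhythmic_LD",
                 per_day_peaks = list(counts), peak_zt = peak_zt)
}

#' Mean daily activity profile of a cohort
#'
#' Raw (unsmoothed) per-bin means across animals of their average-day
#' profiles, with the between-animal SEM; conventionally restricted to
#' animals scored rhythmic in LD.
#'
#' @param cohort List of [activity_series()].
#' @param window_days Days averaged per animal.
#' @param calls Optional tibble of [classify_ld()] rows used to filter.
#' @param only Keep only animals with this `call` (e.g. `"rhythmic_LD"`);
#'   `NULL` keeps all.
#' @return Tibble: `zt`, `mean`, `sem`, `n`.
#' @export
group_daily_profile <- function(cohort, window_days = 5, calls = NULL,
                                only = NULL) {
  if (!is.null(only)) {
    if (is.null(calls))
      calls <- purrr::map_dfr(cohort, classify_ld, window_days = window_days)
    ids <- calls$animal_id[calls$call == only]
    cohort <- purrr::keep(cohort, function(s) attr(s, "animal_id") %in% ids)
  }
  if (length(cohort) == 0L) abort("No animals pass the filter.")
  profs <- purrr::map(cohort, average_day, window_days = window_days)
  mat <- do.call(cbind, purrr::map(profs, "raw_mean"))
  tibble::tibble(
    zt = profs[[1]]$zt,
    mean = rowMeans(mat),
    sem = apply(mat, 1, function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0),
    n = ncol(mat)
  )
}

#' Activity onset and offset from an average-day profile
#'
#' The phase markers are the times the smoothed profile reaches (onset)
#' and falls back to (offset) the median of its 24-h values.  The onset
#' scan starts at the profile's circular minimum and the offset scan at
#' its maximum, which makes both unique on unimodal profiles; crossings
#' are linearly interpolated between bins, and a rise out of a plateau
#' sitting exactly at the threshold is placed at the first
#' above-threshold bin (step-edge rule).
#'
#' @param profile An [average_day()] result.
#' @param min_dwell_h A crossing only counts when the profile stays on
#'   the far side of the threshold for at least this long; filters
#'   transient noise blips near the threshold.
#' @return One-row tibble: `onset_zt`, `offset_zt`, `threshold`.
#' @export
onset_offset <- function(profile, min_dwell_h = 2) {
  stopifnot(inherits(profile, "avg_day_profile"))
  v <- profile$smoothed
  n <- length(v)
  if (diff(range(v)) < 1e-12) abort("Constant profile: no phase defined.")
  thr <- median(v)
  dt <- 24 / n
  dwell <- max(1L, floor(min_dwell_h / dt))
  t_of <- function(i) profile$zt[((i - 1L) %% n) + 1L]
  val <- function(i) v[((i - 1L) %% n) + 1L]
  holds <- function(from, above) {
    idx <- from + seq_len(dwell) - 1L
    if (above) all(vapply(idx, val, numeric(1)) >= thr)
    else all(vapply(idx, val, numeric(1)) <= thr)
  }

  i0 <- which.min(v)
  onset <- NA_real_
  for (k in i0:(i0 + n - 1L)) {
    v1 <- val(k); v2 <- val(k + 1L)
    if (v1 < thr && v2 >= thr && holds(k + 1L, TRUE)) {
      onset <- (t_of(k) + dt * (thr - v1) / (v2 - v1)) %% 24; break
    }
    if (v1 == thr && v2 > thr && holds(k + 1L, TRUE)) {
      onset <- t_of(k + 1L); break
    }
  }
  i1 <- which.max(v)
  offset <- NA_real_
  for (k in i1:(i1 + n - 1L)) {
    v1 <- val(k); v2 <- val(k + 1L)
    if (v1 > thr && v2 <= thr && holds(k + 1L, FALSE)) {
      offset <- (t_of(k) + dt * (v1 - thr) / (v1 - v2)) %% 24; break
    }
  }
  if (is.na(onset) || is.na(offset))
    abort("No threshold crossing found; profile may be degenerate.")
  tibble::tibble(onset_zt = onset, offset_zt = offset, threshold = thr)
}

#' Light-phase vs dark-phase activity of one animal
#'
#' Under a cycling schedule, mean counts per bin are computed separately
#' for light and dark bins over the last `ld_days` complete days.  Under
#' constant conditions the grand per-bin mean over the first
#' `constant_days` days is returned instead.
#'
#' @param series An [activity_series()].
#' @param ld_days Trailing complete LD days to average (>= 3 expected).
#' @param constant_days Days averaged under constant conditions.
#' @return One-row tibble: `animal_id`, `condition`, and `mean_L`/`mean_D`
#'   (LD) or `mean_overall` (DD/LL).
#' @export
light_dark_partition <- function(series, ld_days = 3, constant_days = 10) {
  m <- series_meta(series)
  bins_per_day <- as.integer(24 * 60 / m$bin_minutes)
  n_days <- floor(nrow(series) / bins_per_day)
  if (is_constant_schedule(m$schedule)) {
    if (n_days < constant_days)
      abort(sprintf("Need %d days in constant conditions, have %d.",
                    constant_days, n_days))
    dat <- dplyr::slice_head(tibble::as_tibble(series),
                             n = constant_days * bins_per_day)
    return(tibble::tibble(animal_id = m$animal_id,
                          condition = m$schedule$label,
                          mean_overall = mean(dat$counts, na.rm = TRUE)))
  }
  if (length(unique(series$light)) < 2L)
    abort("Schedule lacks both light states; LD partition undefined.")
  if (n_days < ld_days)
    abort(sprintf("Need %d full LD days, have %d.", ld_days, n_days))
  dat <- dplyr::slice_tail(tibble::as_tibble(series), n = ld_days * bins_per_day)
  tibble::tibble(
    animal_id = m$animal_id,
    condition = m$schedule$label,
    mean_L = mean(dat$counts[dat$light == "ON"], na.rm = TRUE),
    mean_D = mean(dat$counts[dat$light == "OFF"], na.rm = TRUE)
  )
}

#' Activity response to an acute light or dark pulse
#'
#' Compares activity inside the pulse window with the same Zeitgeber-time
#' window averaged over the non-pulse days, so the contrast controls for
#' time-of-day effects.
#'
#' @param series An [activity_series()] whose schedule contains the pulse.
#' @param day 1-based day index of the pulse (defaults to the first pulse
#'   in the schedule).
#' @param start_zt,duration_h Pulse window (defaults from the schedule).
#' @return One-row tibble: `animal_id`, `pulse_window_mean`,
#'   `baseline_mean`, `delta`.
#' @export
pulse_response <- function(series, day = NULL, start_zt = NULL,
                           duration_h = NULL) {
  m <- series_meta(series)
  sch <- m$schedule
  if (nrow(sch$pulses) == 0L) abort("Schedule contains no pulse.")
  p <- sch$pulses[1, ]
  pulse_day <- day %||% (floor(p$start_h / 24) + 1L)
  zt0 <- start_zt %||% zt_of(p$start_h, sch)
  dur <- duration_h %||% (p$end_h - p$start_h)

  bins_per_day <- as.integer(24 * 60 / m$bin_minutes)
  n_days <- floor(nrow(series) / bins_per_day)
  if (n_days < 3) abort("Need at least 2 non-pulse days for the baseline.")
  dat <- tibble::as_tibble(series) |>
    dplyr::mutate(day = floor(.data$time_h / 24) + 1L,
                  in_window = (.data$zt - zt0) %% 24 < dur)
  pulse_mean <- mean(dat$counts[dat$day == pulse_day & dat$in_window], na.rm = TRUE)
  base_mean <- mean(dat$counts[dat$day != pulse_day & dat$in_window &
                                 dat$day <= n_days], na.rm = TRUE)
  if (is.nan(pulse_mean)) abort("Pulse window not covered by the series.")
  tibble::tibble(animal_id = m$animal_id, pulse_window_mean = pulse_mean,
                 baseline_mean = base_mean, delta = pulse_mean - base_mean)
}
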