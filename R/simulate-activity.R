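#' Parameters of a synthetic activity agent
#'
#' The agent's expected count per 5-min bin is
#' \deqn{\lambda(t) = \max\{0,\; b\,(1 + m(t)) + A(t)\,\mathrm{bump}(c(t)) +
#'   d_L\, I_{light}(t)\}}
#' where `b` is the baseline rate, `m(t)` a masking state that jumps by
#' `+mask_gain_dark` at every lights-off and by `-mask_gain_light` at every
#' lights-on and decays exponentially back to 0 with time constant
#' `mask_decay_hours`, `bump()` a von Mises-shaped circadian bump of unit
#' peak height centred on `clock_peak_zt`, `A(t)` the clock amplitude
#' (`clock_amplitude_ld` while entrained, `clock_amplitude_const` in
#' constant conditions, where the clock free-runs with period `tau_free`),
#' and `d_L` an additive drive while lights are on.  Counts are Poisson
#' draws around \eqn{\lambda}.
#'
#' Masking enters multiplicatively on the baseline and the rate clamps at
#' zero, so light-induced suppression can silence an agent but never
#' produce negative rates.
#'
#' @param baseline_rate Expected counts per 5-min bin with all drives off.
#' @param clock_amplitude_ld,clock_amplitude_const Peak height of the clock
#'   bump (counts/bin) while entrained / in constant conditions.
#' @param clock_peak_zt ZT hours of the bump centre.
#' @param clock_width Concentration (von Mises kappa) of the bump.
#' @param tau_free Free-running period in hours (must lie in (16, 32)).
#' @param light_drive Additive counts/bin while lights are ON (may be
#'   negative; the rate still clamps at 0).
#' @param mask_gain_dark,mask_gain_light Masking jumps at lights-off /
#'   lights-on (both >= 0).
#' @param mask_decay_hours Masking decay time constant (> 0).
#' @return An `agent_params` list.
#' @export
agent_params <- function(baseline_rate = 2,
                         clock_amplitude_ld = 0,
                         clock_amplitude_const = clock_amplitude_ld,
                         clock_peak_zt = 9,
                         clock_width = 2.5,
                         tau_free = 24.2,
                         light_drive = 0,
                         mask_gain_dark = 0,
                         mask_gain_light = 0,
                         mask_decay_hours = 1.5) {
  if (baseline_rate < 0) abort("`baseline_rate` must be >= 0.")
  if (clock_amplitude_ld < 0 || clock_amplitude_const < 0)
    abort("Clock amplitudes must be >= 0.")
  if (mask_gain_dark < 0 || mask_gain_light < 0)
    abort("Masking gains must be >= 0.")
  if (mask_decay_hours <= 0) abort("`mask_decay_hours` must be > 0.")
  if (tau_free <= 16 || tau_free >= 32)
    abort("`tau_free` must lie in (16, 32) hours.")
  structure(list(
    baseline_rate = baseline_rate,
    clock_amplitude_ld = clock_amplitude_ld,
    clock_amplitude_const = clock_amplitude_const,
    clock_peak_zt = clock_peak_zt,
    clock_width = clock_width,
    tau_free = tau_free,
    light_drive = light_drive,
    mask_gain_dark = mask_gain_dark,
    mask_gain_light = mask_gain_light,
    mask_decay_hours = mask_decay_hours
  ), class = "agent_params")
}

#' Genotype presets for the cohort simulator
#'
#' Four behavioural archetypes cover the contrasts the analyses must
#' resolve: a diurnal clock-driven wild type; a clock-output null whose
#' nocturnal activity is pure masking (75% of agents) or noise (25%);
#' a light-driven mutant that is diurnal under LD but loses rhythm in
#' constant conditions; and a long-period variant (tau 45 min longer than
#' wild type).  All numeric values are simulator choices tuned to
#' reproduce the qualitative contrasts, not measurements.
#'
#' @param name One of `"wt"`, `"pdf_null"`, `"cry_m"`, `"pdf_rk"`.
#' @return A `genotype_preset`: list with `name`, `params`
#'   ([agent_params()]), and `ld_rhythmic_fraction` (share of agents given
#'   the preset's time-of-day drive; the rest are constant-rate Poisson).
#' @export
genotype_preset <- function(name) {
  presets <- list(
    wt = list(
      params = agent_params(baseline_rate = 2, clock_amplitude_ld = 6,
                            clock_amplitude_const = 6, clock_peak_zt = 9,
                            tau_free = 24.2, mask_gain_dark = 0.5,
                            mask_gain_light = 0.5, mask_decay_hours = 1.5),
      ld_rhythmic_fraction = 1),
    pdf_null = list(
      params = agent_params(baseline_rate = 2, clock_amplitude_ld = 0,
                            clock_amplitude_const = 0,
                            mask_gain_dark = 4, mask_gain_light = 4,
                            mask_decay_hours = 2),
      ld_rhythmic_fraction = 0.75),
    cry_m = list(
      params = agent_params(baseline_rate = 2, clock_amplitude_ld = 6,
                            clock_amplitude_const = 0, clock_peak_zt = 7,
                            tau_free = 24.2, mask_gain_dark = 0.5,
                            mask_gain_light = 0.5),
      ld_rhythmic_fraction = 1),
    pdf_rk = list(
      params = agent_params(baseline_rate = 2, clock_amplitude_ld = 6,
                            clock_amplitude_const = 6, clock_peak_zt = 9,
                            tau_free = 24.95, mask_gain_dark = 0.5,
                            mask_gain_light = 0.5),
      ld_rhythmic_fraction = 1)
  )
  if (!name %in% names(presets))
    abort(sprintf("Unknown preset '%s'. Available: %s.", name,
                  paste(names(presets), collapse = ", ")))
  structure(c(list(name = name), presets[[name]]), class = "genotype_preset")
}

# Clock time (hours on a 24-h dial) at each bin start: equals ZT while the
# light program cycles, free-runs at tau_free through constant blocks.
clock_time <- function(time_h, schedule, tau_free) {
  blocks <- attr(schedule, "blocks")
  if (is.null(blocks)) {
    blocks <- data.frame(label = schedule$label, start_h = 0,
                         end_h = schedule$span_h,
                         constant = is_constant_schedule(schedule))
  }
  ct <- numeric(length(time_h))
  phase0 <- schedule$t0_zt
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    idx <- time_h >= b$start_h - 1e-9 & time_h < b$end_h - 1e-9
    zt_start <- (b$start_h + schedule$t0_zt) %% 24
    if (b$constant) {
      ct[idx] <- (zt_start + (time_h[idx] - b$start_h) * 24 / tau_free) %% 24
    } else {
      ct[idx] <- (schedule$t0_zt + time_h[idx]) %% 24
    }
  }
  ct
}

circ_bump <- function(clock_h, peak_zt, kappa) {
  exp(kappa * (cos(2 * pi * (clock_h - peak_zt) / 24) - 1))
}

# Masking state m(t): superposition of exponentially decaying jumps, one
# per light transition.
masking_state <- function(time_h, schedule, g_dark, g_light, tau_m) {
  m <- numeric(length(time_h))
  if (g_dark == 0 && g_light == 0) return(m)
  tr <- schedule_transitions(schedule)
  if (nrow(tr) == 0L) return(m)
  jump <- ifelse(tr$to_state == "OFF", g_dark, -g_light)
  for (i in seq_len(nrow(tr))) {
    idx <- time_h >= tr$time_h[i]
    m[idx] <- m[idx] + jump[i] * exp(-(time_h[idx] - tr$time_h[i]) / tau_m)
  }
  m
}

#' Deterministic expected rate of an agent over a schedule
#'
#' The per-bin Poisson mean before any noise is drawn; useful for checking
#' transient dynamics analytically.
#'
#' @param params An [agent_params()].
#' @param schedule A [light_schedule()].
#' @param bin_minutes Bin length in minutes.
#' @return Tibble with `time_h`, `zt`, `light`, and `rate` (expected counts
#'   per bin of `bin_minutes`).
#' @export
agent_rate <- function(params, schedule, bin_minutes = 5) {
  stopifnot(inherits(params, "agent_params"), inherits(schedule, "light_schedule"))
  n <- floor(schedule$span_h * 60 / bin_minutes)
  time_h <- (seq_len(n) - 1L) * bin_minutes / 60
  light <- light_state_at(time_h, schedule)
  blocks <- attr(schedule, "blocks")
  constant_here <- if (is.null(blocks)) {
    rep(is_constant_schedule(schedule), n)
  } else {
    const <- logical(n)
    for (i in seq_len(nrow(blocks)))
      const[time_h >= blocks$start_h[i] - 1e-9 & time_h < blocks$end_h[i] - 1e-9] <-
        blocks$constant[i]
    const
  }
  amp <- ifelse(constant_here, params$clock_amplitude_const, params$clock_amplitude_ld)
  ct <- clock_time(time_h, schedule, params$tau_free)
  m <- masking_state(time_h, schedule, params$mask_gain_dark,
                     params$mask_gain_light, params$mask_decay_hours)
  lam <- params$baseline_rate * (1 + m) +
    amp * circ_bump(ct, params$clock_peak_zt, params$clock_width) +
    params$light_drive * (light == "ON")
  lam <- pmax(0, lam) * bin_minutes / 5
  tibble::tibble(time_h = time_h, zt = zt_of(time_h, schedule),
                 light = light, rate = lam)
}

#' Simulate one activity agent
#'
#' Draws per-bin Poisson counts around the deterministic rate of
#' [agent_rate()].  Deterministic given `seed`.
#'
#' @inheritParams agent_rate
#' @param seed Integer RNG seed.
#' @param animal_id,genotype Identifiers for the resulting series.
#' @return An [activity_series()].
#' @export
simulate_agent <- function(params, schedule, seed = 1, bin_minutes = 5,
                           animal_id = "sim", genotype = "sim") {
  r <- agent_rate(params, schedule, bin_minutes)
  counts <- withr::with_seed(seed, rpois(nrow(r), r$rate))
  activity_series(counts, schedule, bin_minutes, animal_id, genotype)
}

#' Simulate a cohort of agents from a genotype preset
#'
#' Per-animal seeds derive deterministically from the cohort seed and the
#' animal index, so cohorts are reproducible independent of iteration
#' order.  A share `1 - ld_rhythmic_fraction` of agents is stripped of all
#' time-of-day drive (pure constant-rate Poisson noise).
#'
#' @param preset A [genotype_preset()] or a preset name.
#' @param n Number of animals (>= 1).
#' @param schedule A [light_schedule()].
#' @param seed Cohort seed.
#' @param bin_minutes Bin length in minutes.
#' @return List of `n` [activity_series()].
#' @export
simulate_cohort <- function(preset, n, schedule, seed = 1, bin_minutes = 5) {
  if (is.character(preset)) preset <- genotype_preset(preset)
  stopifnot(inherits(preset, "genotype_preset"))
  if (n < 1) abort("`n` must be >= 1.")
  n_drive <- round(n * preset$ld_rhythmic_fraction)
  purrr::map(seq_len(n), function(i) {
    p <- preset$params
    if (i > n_drive) {
      # noise-only agent: baseline Poisson, no clock, no masking
      p <- agent_params(baseline_rate = p$baseline_rate,
                        tau_free = p$tau_free)
    }
    simulate_agent(p, schedule, seed = derive_seed(seed, i),
                   bin_minutes = bin_minutes,
                   animal_id = sprintf("%s_%02d", preset$name, i),
                   genotype = preset$name)
  })
}

# Splittable counter-style seed derivation; keeps results independent of
# the order animals are generated in and below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 30269) %% 2147483587)
}
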