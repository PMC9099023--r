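test_that("average-day profiles fold, average and smooth correctly", {
  # constant series -> flat profile, smoothing a no-op
  s <- series_from_day(rep(4, 288), days = 5)
  prof <- average_day(s, 5, 20)
  expect_true(all(prof$raw_mean == 4))
  expect_equal(prof$smoothed, prof$raw_mean, tolerance = 1e-12)
  # a daily spike at ZT8 smooths to the Gaussian kernel centred at ZT8
  day <- rep(0, 288); day[8 * 12 + 1] <- 288
  prof2 <- average_day(series_from_day(day, days = 5), 5, 20)
  sig_bins <- 20 / 5
  half <- ceiling(5 * sig_bins)         # kernel support used by the smoother
  off <- seq_len(288) - (8 * 12 + 1)
  off <- pmin(abs(off), 288 - abs(off))
  base_k <- exp(-((-half:half)^2) / (2 * sig_bins^2))
  kern <- ifelse(off <= half, exp(-off^2 / (2 * sig_bins^2)) / sum(base_k) * 288, 0)
  expect_equal(prof2$smoothed, kern, tolerance = 1e-9)
  expect_error(average_day(series_from_day(rep(1, 288), days = 3), 5),
               "3 full")
})

test_that("circular smoothing conserves the profile sum", {
  set.seed(21)
  for (sig in c(5, 20, 60)) {
    y <- rpois(288, 3)
    expect_equal(sum(chronobug:::smooth_circular(y, sig / 5)), sum(y),
                 tolerance = 1e-9)
  }
})

test_that("LD scoring separates unimodal, noise-only and bimodal agents", {
  sch <- light_schedule("LD18:6", 5)
  wt_calls <- vapply(simulate_cohort("wt", 20, sch, seed = 7),
                     function(s) classify_ld(s)$call, character(1))
  expect_gte(mean(wt_calls == "rhythmic_LD"), 0.9)
  noise_calls <- vapply(1:20, function(i)
    classify_ld(simulate_agent(agent_params(baseline_rate = 3), sch,
                               seed = i))$call, character(1))
  expect_gte(mean(noise_calls == "arrhythmic_LD"), 0.9)
  # bimodal: sum of two Poisson agents with bumps 8 h apart
  pa <- agent_params(baseline_rate = 2, clock_amplitude_ld = 4, clock_peak_zt = 5)
  pb <- agent_params(baseline_rate = 1e-4, clock_amplitude_ld = 4, clock_peak_zt = 13)
  lam <- agent_rate(pa, sch)$rate + agent_rate(pb, sch)$rate
  set.seed(3)
  bi <- activity_series(rpois(length(lam), lam), sch, 5, "bimodal")
  expect_identical(classify_ld(bi)$call, "arrhythmic_LD")
})

test_that("LD scoring is invariant to uniform count rescaling and flags inactive animals", {
  sch <- light_schedule("LD18:6", 5)
  s <- simulate_agent(genotype_preset("wt")$params, sch, seed = 4)
  s10 <- activity_series(s$counts * 10, sch, 5, "x10")
  expect_identical(classify_ld(s)$call, classify_ld(s10)$call)
  dead <- activity_series(rep(0, 5 * 288), sch, 5, "dead")
  expect_message(res <- classify_ld(dead), "inactive")
  expect_identical(res$call, "inactive")
})

test_that("cohort profiles average raw counts with between-animal SEM", {
  sch <- light_schedule("LD18:6", 5)
  s <- simulate_agent(genotype_preset("wt")$params, sch, seed = 2)
  g1 <- group_daily_profile(list(s), 5)
  expect_equal(g1$mean, average_day(s, 5)$raw_mean)
  expect_true(all(g1$sem == 0))
  g2 <- group_daily_profile(list(s, s), 5)
  expect_equal(g2$mean, g1$mean)
  expect_true(all(g2$sem == 0))
  expect_error(group_daily_profile(list(), 5), "No animals")
  # a WT cohort shows a single mid-photophase maximum
  g <- group_daily_profile(simulate_cohort("wt", 16, sch, seed = 5), 5,
                           only = "rhythmic_LD")
  expect_lt(abs(g$zt[which.max(chronobug:::smooth_circular(g$mean, 4))] - 9), 2)
})

test_that("onset and offset hit analytic values on square and triangle profiles", {
  low <- 2; high <- 10
  zt <- (0:287) / 12
  square <- ifelse(zt >= 4 & zt < 12, high, low)
  oo <- onset_offset(profile_from_values(square))
  expect_equal(oo$onset_zt, 4)
  expect_equal(oo$offset_zt, 12)
  tri <- 10 - (8 / 12) * abs(zt - 12)
  oo2 <- onset_offset(profile_from_values(tri))
  expect_equal(oo2$onset_zt, 6)
  expect_equal(oo2$offset_zt, 18)
  expect_error(onset_offset(profile_from_values(rep(3, 288))), "no phase")
})

test_that("onset/offset are equivariant under circular shifts", {
  set.seed(8)
  base <- 2 + 8 * exp(2 * (cos(2 * pi * ((0:287) / 12 - 9) / 24) - 1)) +
    rnorm(288, 0, 0.1)
  oo0 <- onset_offset(profile_from_values(base))
  for (k in c(12, 60, 200)) {
    shifted <- c(tail(base, -k), head(base, k))   # delay by k bins... advance
    oo <- onset_offset(profile_from_values(shifted))
    expected <- ((-k / 12 + 12) %% 24) - 12
    expect_equal(wrap_diff_h(oo$onset_zt, oo0$onset_zt), expected,
                 tolerance = 1e-9)
    expect_equal(wrap_diff_h(oo$offset_zt, oo0$offset_zt), expected,
                 tolerance = 1e-9)
  }
})

test_that("light/dark partition averages the right bins", {
  sch <- light_schedule("LD18:6", 5)
  # active only in the dark
  day <- ifelse((0:287) / 12 >= 18, 6, 0)
  s <- series_from_day(day, days = 5)
  lp <- light_dark_partition(s)
  expect_equal(lp$mean_L, 0)
  expect_equal(lp$mean_D, 6)
  # constant conditions: grand mean over 10 days
  sdd <- simulate_agent(agent_params(baseline_rate = 2.5),
                        light_schedule("DD", 10), seed = 3)
  lp2 <- light_dark_partition(sdd)
  expect_lt(abs(lp2$mean_overall - 2.5), 0.1)
  expect_error(light_dark_partition(series_from_day(day, days = 2)), "3 full")
})

test_that("pulse responses compare the pulse window with matched baselines", {
  pl <- data.frame(day = 4, start_zt = 8, duration_h = 2, state = "OFF")
  sch <- light_schedule("LD18:6", 5, pulses = pl)
  # zero-masking agent: delta consistent with zero
  deltas <- vapply(1:20, function(i)
    pulse_response(simulate_agent(agent_params(baseline_rate = 4), sch,
                                  seed = i))$delta, numeric(1))
  expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(length(deltas)))
  # masking agent responds to a dark pulse with extra activity
  pn <- genotype_preset("pdf_null")$params
  d <- vapply(1:20, function(i)
    pulse_response(simulate_agent(pn, sch, seed = i))$delta, numeric(1))
  expect_gt(mean(d), 0)
  expect_error(pulse_response(simulate_agent(pn, light_schedule("LD18:6", 5),
                                             seed = 1)),
               "no pulse")
})
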