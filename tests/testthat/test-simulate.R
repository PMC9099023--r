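test_that("a drive-free agent is plain Poisson at the baseline rate", {
  sch <- light_schedule("DD", 12)
  s <- simulate_agent(agent_params(baseline_rate = 3), sch, seed = 5)
  n <- nrow(s)
  expect_lt(abs(mean(s$counts) - 3), 3 * sqrt(3 / n))
  # mean/variance ratio ~ 1 (Poisson) at n >= 1e5 pooled bins
  pool <- unlist(lapply(1:30, function(i)
    simulate_agent(agent_params(baseline_rate = 3),
                   light_schedule("DD", 12), seed = i)$counts))
  expect_gt(length(pool), 1e5)
  expect_lt(abs(var(pool) / mean(pool) - 1), 0.02)
})

test_that("identical seeds give bit-identical agents; seeds derive stably", {
  sch <- light_schedule("LD18:6", 5)
  p <- genotype_preset("wt")$params
  expect_identical(simulate_agent(p, sch, seed = 9)$counts,
                   simulate_agent(p, sch, seed = 9)$counts)
  co1 <- simulate_cohort("wt", 4, sch, seed = 3)
  co2 <- simulate_cohort("wt", 4, sch, seed = 3)
  expect_identical(cohort_long(co1), cohort_long(co2))
})

test_that("preset and argument validation fail loudly", {
  expect_error(genotype_preset("nope"), "wt.*pdf_null")
  expect_error(simulate_cohort("wt", 0, light_schedule("DD", 2)), ">= 1")
  expect_error(agent_params(baseline_rate = -1), ">= 0")
  expect_error(agent_params(tau_free = 40), "16, 32")
})

test_that("masking-only agents are nocturnal in LD and dark activity decays over long nights", {
  pn <- genotype_preset("pdf_null")$params
  ok <- vapply(1:50, function(i) {
    lp <- light_dark_partition(simulate_agent(pn, light_schedule("LD18:6", 5),
                                              seed = i))
    lp$mean_D > lp$mean_L
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # LD9:15: the lights-off transient has decayed late in the 15-h night
  r <- agent_rate(pn, light_schedule("LD9:15", 4))
  night <- dplyr::filter(r, light == "OFF", time_h >= 24)
  early <- mean(night$rate[(night$zt - 9) %% 24 < 5])
  late <- mean(night$rate[(night$zt - 9) %% 24 >= 10])
  expect_lt(late, early)
})

test_that("masking transient decays to 5% of its jump within 3 tau_m and DD/LL agree", {
  pn <- genotype_preset("pdf_null")$params
  sch <- append_schedule(light_schedule("LD18:6", 2), "DD", 2)
  r <- agent_rate(pn, sch)
  t_off <- 24 + 18                       # final lights-off before release
  base <- pn$baseline_rate
  jump0 <- r$rate[r$time_h == t_off] - base
  rem <- r$rate[r$time_h == t_off + 3 * pn$mask_decay_hours] - base
  expect_lt(rem / jump0, 0.05)
  expect_gt(rem / jump0, 0.02)           # exponential, not instantaneous
  # long-run DD and LL means differ only through the initial transient
  sdd <- append_schedule(light_schedule("LD18:6", 3), "DD", 10)
  sll <- append_schedule(light_schedule("LD18:6", 3), "LL", 10)
  mdd <- mean(agent_rate(pn, sdd)$rate[(3 * 288 + 1):(13 * 288)])
  mll <- mean(agent_rate(pn, sll)$rate[(3 * 288 + 1):(13 * 288)])
  expect_lt(abs(mdd - mll) / mdd, 0.1)
})

test_that("photoperiodic cohorts follow the logistic and honor the step limit", {
  m <- photoperiodic_model(p_min = 0, p_max = 1, cdl_true = 14, slope = 400,
                           n_per_condition = 30, photoperiods = c(12, 16))
  rec <- simulate_photoperiodic_cohort(m, seed = 2)
  cur <- response_curve(rec)
  expect_equal(cur$proportion[cur$photoperiod_light_h == 12], 1)
  expect_equal(cur$proportion[cur$photoperiod_light_h == 16], 0)
  expect_true(all(cur$n == 30))
  # decreasing incidence in photoperiod for a graded curve
  m2 <- photoperiodic_model(cdl_true = 16.4, slope = 3, n_per_condition = 30,
                            photoperiods = 8:18)
  neg <- vapply(1:40, function(i) {
    cc <- response_curve(simulate_photoperiodic_cohort(m2, seed = i))
    cor(cc$photoperiod_light_h, cc$proportion, method = "spearman") < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)
})

test_that("qPCR simulator encodes ratios and efficiencies exactly at zero noise", {
  sim <- simulate_qpcr(c(cal = 1, up = 8), noise_sd_cq = 0)
  cqw <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(sim$cq, sample_id, gene),
                     cq = mean(cq), .groups = "drop"),
    names_from = gene, values_from = cq)
  expect_equal(cqw$target[cqw$sample_id == "up"],
               cqw$target[cqw$sample_id == "cal"] - 3)  # log2(8) cycles
  dil <- dplyr::filter(sim$dilution, gene == "target")
  expect_equal(unname(coef(lm(cq ~ log10_dilution, dil))[2]),
               -1 / log10(2), tolerance = 1e-12)
  expect_error(simulate_qpcr(c(a = -1)), "> 0")
})

test_that("brain-image simulator produces exact uniform background and valid blobs", {
  img <- simulate_brain_image(background_level = 100, noise_sd = 0)
  expect_true(all(img$pixels == 100))
  expect_error(simulate_brain_image(cbind(10, 10), -5), ">= 0")
  expect_error(simulate_brain_image(scale_um_per_px = 0), "> 0")
  img2 <- simulate_brain_image(cbind(50, 50), 40, cell_sigma_um = 5,
                               background_level = 10, noise_sd = 0,
                               dim_px = c(100, 100))
  expect_equal(max(img2$pixels), 50, tolerance = 0.01)
  expect_true(img2$masks[[1]][50, 50])
})
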