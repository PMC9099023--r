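test_that("the diapause call implements the full reproductive-record truth table", {
  tt <- expand.grid(laid_eggs = c(TRUE, FALSE),
                    mature_eggs_present = c(TRUE, FALSE),
                    vitellogenic_oocytes_present = c(TRUE, FALSE))
  calls <- call_diapause(tt)
  # diapause iff nothing laid AND no mature eggs AND no vitellogenic oocytes
  expect_equal(calls, with(tt, !laid_eggs & !mature_eggs_present &
                             !vitellogenic_oocytes_present))
  bad <- tibble::tibble(laid_eggs = FALSE, mature_eggs_present = NA,
                        vitellogenic_oocytes_present = NA)
  expect_error(call_diapause(bad), "dissection")
})

test_that("response curves carry binomial proportions and SEMs", {
  rec <- tibble::tibble(
    genotype = "WT",
    photoperiod_light_h = rep(c(10, 14), each = 30),
    laid_eggs = c(rep(FALSE, 30), rep(c(TRUE, FALSE), 15)),
    mature_eggs_present = FALSE,
    vitellogenic_oocytes_present = FALSE)
  cur <- response_curve(rec)
  expect_equal(cur$proportion[cur$photoperiod_light_h == 10], 1)
  expect_equal(cur$sem[cur$photoperiod_light_h == 10], 0)
  expect_equal(cur$proportion[cur$photoperiod_light_h == 14], 0.5)
  expect_equal(cur$sem[cur$photoperiod_light_h == 14], sqrt(0.25 / 30),
               tolerance = 1e-12)
})

test_that("CDL sits inside a hard step and degenerate curves are flagged", {
  cur <- tibble::tibble(photoperiod_light_h = 10:18,
                        n = 30,
                        k_diapause = ifelse(10:18 <= 14, 30, 0))
  fit <- fit_cdl(cur, bootstrap_b = 0)
  expect_gt(fit$cdl_h, 14)
  expect_lt(fit$cdl_h, 15)
  expect_false(fit$degenerate)
  all_d <- dplyr::mutate(cur, k_diapause = n)
  fit2 <- fit_cdl(all_d, bootstrap_b = 0)
  expect_true(fit2$degenerate)
  expect_true(is.na(fit2$cdl_h))
  expect_error(fit_cdl(cur[1:3, ]), "4 photoperiods")
})

test_that("fitted curves are monotone non-increasing in day length", {
  set.seed(4)
  m <- photoperiodic_model(cdl_true = 15, slope = 2, n_per_condition = 30)
  fit <- fit_cdl(response_curve(simulate_photoperiodic_cohort(m, seed = 8)),
                 bootstrap_b = 0)
  L <- seq(8, 18, 0.1)
  p <- chronobug:::ppr_logistic(L, unlist(fit$params))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("binomial and least-squares fits agree on clean curves", {
  m <- photoperiodic_model(cdl_true = 16, slope = 3, n_per_condition = 200)
  cur <- response_curve(simulate_photoperiodic_cohort(m, seed = 3))
  fb <- fit_cdl(cur, bootstrap_b = 0, method = "binomial")
  fl <- fit_cdl(cur, bootstrap_b = 0, method = "least_squares")
  expect_lt(abs(fb$cdl_h - fl$cdl_h), 0.1)
})

test_that("CDL comparisons difference the fits and guard their modes", {
  m <- photoperiodic_model(cdl_true = 16.4, slope = 3, n_per_condition = 30)
  f1 <- fit_cdl(response_curve(simulate_photoperiodic_cohort(m, seed = 1)),
                bootstrap_b = 100, seed = 2)
  cmp0 <- compare_cdl(f1, f1)
  expect_equal(cmp0$delta_h, 0)
  f2 <- fit_cdl(response_curve(simulate_photoperiodic_cohort(m, seed = 1)),
                bootstrap_b = 100, seed = 2, mode = "midpoint")
  expect_error(compare_cdl(f1, f2), "modes differ")
  degen <- fit_cdl(tibble::tibble(photoperiod_light_h = 10:14, n = 30,
                                  k_diapause = 30), bootstrap_b = 0)
  expect_error(compare_cdl(f1, degen), "degenerate")
})

test_that("tidy and glance expose the CDL fit in broom shape", {
  m <- photoperiodic_model(cdl_true = 16, slope = 3, n_per_condition = 30)
  fit <- fit_cdl(response_curve(simulate_photoperiodic_cohort(m, seed = 4)),
                 bootstrap_b = 50, seed = 3)
  td <- tidy(fit)
  expect_setequal(td$term, c("p_min", "p_max", "slope", "l50"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_false(gl$degenerate)
  expect_true(gl$ci_lo < gl$cdl_h, gl$cdl_h < gl$ci_hi)
})
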