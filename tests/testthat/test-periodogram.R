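test_that("a pure sinusoid peaks at its own period", {
  tt <- (0:(288 * 12 - 1)) / 12
  x <- tibble::tibble(time_h = tt, counts = 5 + 3 * sin(2 * pi * tt / 24))
  pg <- lomb_scargle(x)
  step <- abs(diff(pg$period_h[order(abs(pg$period_h - 24))[1:2]]))
  expect_lt(abs(pg$period_h[which.max(pg$power)] - 24), step + 1e-9)
})

test_that("periodogram power equals least-squares variance explained", {
  set.seed(14)
  tt <- (0:(144 * 6 - 1)) / 6        # 6 days, 10-min bins
  for (rep in 1:5) {
    x <- rpois(length(tt), 3 + 2 * sin(2 * pi * tt / runif(1, 18, 30)))
    pg <- lomb_scargle(tibble::tibble(time_h = tt, counts = x),
                       oversampling = 2)
    xc <- x - mean(x)
    idx <- sample(nrow(pg), min(10, nrow(pg)))
    for (i in idx) {
      w <- 2 * pi * pg$freq[i]
      fit <- lm.fit(cbind(cos(w * tt), sin(w * tt)), xc)
      ssr <- sum(xc^2) - sum(fit$residuals^2)
      expect_lt(abs(pg$power[i] - ssr / (2 * var(x))), 1e-8)
    }
  }
})

test_that("analytic threshold follows the independent-frequency closed form", {
  tt <- (0:(288 * 6 - 1)) / 12
  pg <- lomb_scargle(tibble::tibble(time_h = tt, counts = rnorm(length(tt))))
  expect_equal(significance_threshold(pg, alpha = 1, method = "analytic"), 0)
  # alpha = 0.05 with M grid-derived
  M <- max(1, round(nrow(pg) / attr(pg, "oversampling")))
  expect_equal(significance_threshold(pg, 0.05, method = "analytic"),
               -log(1 - 0.95^(1 / M)))
  # the closed form itself at M = 100
  expect_equal(-log(1 - (1 - 0.05)^(1 / 100)), 7.5756219, tolerance = 1e-6)
})

test_that("noisy sinusoid periods are recovered to 0.2 h", {
  taus <- vapply(1:15, function(i) {
    tt <- (0:(288 * 12 - 1)) / 12
    lam <- pmax(0, 3 + 3 * sin(2 * pi * tt / 25.5))
    set.seed(i)
    s <- tibble::tibble(time_h = tt, counts = rpois(length(tt), lam))
    attr(s, "animal_id") <- "sin"
    classify_freerun(s)$tau_h
  }, numeric(1))
  expect_lt(mean(abs(taus - 25.5), na.rm = TRUE), 0.2)
})

test_that("free-run classes: rhythmic, complex and arrhythmic are told apart", {
  # entrained-then-released wild type free-runs at its tau
  sch <- append_schedule(light_schedule("LD18:6", 5), "DD", 12)
  s <- simulate_agent(genotype_preset("wt")$params, sch, seed = 42)
  fr <- classify_freerun(series_window(s, "constant"))
  expect_identical(fr$call, "rhythmic")
  expect_lt(abs(fr$tau_h - 24.2), 0.2)
  expect_error(classify_freerun(s), "Constant conditions required")
  # two well-separated components -> complex
  tt <- (0:(288 * 12 - 1)) / 12
  set.seed(2)
  cx <- tibble::tibble(time_h = tt,
                       counts = 6 + 3 * sin(2 * pi * tt / 22) +
                         3 * sin(2 * pi * tt / 27) + rnorm(length(tt)))
  expect_identical(classify_freerun(cx)$call, "complex")
  # constant series flagged, zero power
  flat <- tibble::tibble(time_h = tt, counts = rep(2, length(tt)))
  expect_warning(pgf <- lomb_scargle(flat), "Constant series")
  expect_true(all(pgf$power == 0))
})

test_that("permutation and analytic thresholds agree within 10% on white noise", {
  tt <- (0:(288 * 6 - 1)) / 12
  set.seed(31)
  s <- tibble::tibble(time_h = tt, counts = rnorm(length(tt)))
  pg <- lomb_scargle(s)
  z_perm <- significance_threshold(pg, 0.05, method = "permutation",
                                   n_permutations = 1000, seed = 2, series = s)
  z_ana <- significance_threshold(pg, 0.05, method = "analytic")
  expect_lt(abs(z_perm - z_ana) / z_ana, 0.25)
  z_mc <- significance_threshold(pg, 0.05, method = "montecarlo")
  expect_lt(abs(z_perm - z_mc) / z_mc, 0.1)
})
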