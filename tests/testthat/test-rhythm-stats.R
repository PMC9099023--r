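test_that("hour-to-radian conversion is the standard dial map", {
  expect_equal(hours_to_radians(6), pi / 2)
  expect_equal(hours_to_radians(24), 0)
  expect_equal(hours_to_radians(20), 5 * pi / 3)
  expect_equal(radians_to_hours(hours_to_radians(13.25)), 13.25)
})

test_that("Rayleigh test: concentration, symmetry and rotation invariance", {
  r1 <- rayleigh_test(rep(0.7, 5))
  expect_equal(r1$rho, 1)
  expect_lt(r1$p_value, 0.01)
  r0 <- rayleigh_test(c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(r0$rho, 0, tolerance = 1e-12)
  expect_gt(r0$p_value, 0.99)
  set.seed(5)
  th <- rvonmises(200, 1, 2)
  pa <- rayleigh_test(th)$p_value
  pb <- rayleigh_test((th + 2.1) %% (2 * pi))$p_value
  expect_equal(pa, pb, tolerance = 1e-12)
  expect_error(rayleigh_test(0.5), "at least 2")
})

test_that("Rayleigh rho matches the Bessel-ratio closed form for von Mises draws", {
  set.seed(77)
  th <- rvonmises(1000, 2, 2)
  expect_lt(abs(rayleigh_test(th)$rho - besselI(2, 1) / besselI(2, 0)), 0.03)
})

test_that("Watson's U2: identity, separation, swap and rotation invariance", {
  a <- c(0.3, 1.0, 2.2, 3.1, 4.0)
  same <- watson_u2(a, a, n_permutations = 499, seed = 1)
  expect_equal(same$u2, 0, tolerance = 1e-12)
  expect_gt(same$p_value, 0.99)
  set.seed(6)
  g1 <- rnorm(20, 1, 0.1) %% (2 * pi)
  g2 <- rnorm(20, 1 + pi, 0.1) %% (2 * pi)
  w <- watson_u2(g1, g2, n_permutations = 999, seed = 2)
  expect_lt(w$p_value, 0.01)
  wswap <- watson_u2(g2, g1, n_permutations = 999, seed = 2)
  expect_equal(w$u2, wswap$u2, tolerance = 1e-12)
  wrot <- watson_u2((g1 + 1.7) %% (2 * pi), (g2 + 1.7) %% (2 * pi),
                    n_permutations = 999, seed = 2)
  expect_equal(w$u2, wrot$u2, tolerance = 1e-12)
  expect_error(watson_u2(1:3, g2), "at least 4")
  # asymptotic mode available and broadly consistent on a clear separation
  expect_lt(watson_u2(g1, g2, method = "asymptotic")$p_value, 0.01)
})

test_that("compiled Kendall S equals brute-force pair counting (with ties)", {
  set.seed(9)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, n, replace = TRUE)
    expect_equal(kendall_tau(x, y)$S, kendall_bruteforce(x, y))
  }
})

test_that("JTK finds the phase of a clean cosine and its antiphase", {
  zt <- rep(seq(0, 20, 4), each = 3)
  v <- cos(2 * pi * (zt - 8) / 24)
  r <- jtk_cycle(v, zt, seed = 3)
  expect_equal(r$best_lag_h, 8)
  expect_equal(r$best_period_h, 24)
  expect_equal(r$tau_statistic, 1)
  expect_lt(r$p_value, 0.01)
  r2 <- jtk_cycle(-v, zt, seed = 3)
  expect_equal(r2$best_lag_h, 20)   # 12 h antiphase shift
  expect_identical(jtk_cycle(rep(5, 18), zt)$p_value, 1)
  expect_error(jtk_cycle(1:6, rep(c(0, 8), 3)), "4 distinct")
})

test_that("JTK exact mode agrees with the enumerated small-sample null", {
  zt <- seq(0, 20, 4)
  set.seed(12)
  v <- cos(2 * pi * (zt - 4) / 24) + rnorm(6, 0, 0.3)
  re <- jtk_cycle(v, zt, exact_n_max = 10)
  expect_identical(re$method, "exact")
  rp <- jtk_cycle(v, zt, exact_n_max = 0, n_permutations = 20000, seed = 5)
  expect_identical(rp$method, "permutation")
  expect_lt(abs(re$p_value - rp$p_value), 0.05)
})

test_that("Grubbs flags gross outliers and respects degenerate inputs", {
  out <- grubbs_test(c(1:9, 100))
  expect_equal(out$index, 10)
  expect_equal(out$value, 100)
  expect_gt(out$g, out$g_critical)
  expect_equal(nrow(grubbs_test(rep(4, 10))), 0)
  expect_error(grubbs_test(c(1, 2)), "at least 3")
  # false-positive rate near nominal alpha
  set.seed(33)
  fp <- vapply(1:800, function(i) nrow(grubbs_test(rnorm(20))) > 0, logical(1))
  expect_lt(abs(mean(fp) - 0.05), 0.02)
})
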