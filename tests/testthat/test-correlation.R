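test_that("g(r) is unbiased for complete spatial randomness", {
  set.seed(61)
  pts <- cbind(runif(10000, 0, 2000), runif(10000, 0, 1500))
  g <- pair_autocorrelation(pts, c(0, 2000, 0, 1500), r_max = 500)
  expect_lt(abs(mean(g$g) - 1), 0.05)
})

test_that("FFT estimator agrees with the brute-force oracle within 2%", {
  set.seed(62)
  n <- 800
  pts <- cbind(runif(n, 0, 1000), runif(n, 0, 800))
  gf <- pair_autocorrelation(pts, c(0, 1000, 0, 800), r_max = 400,
                             bin_width = 20, grid = 2.5)
  gb <- oracle_autocorrelation(pts, 1000, 800, r_max = 400, bin_width = 20)
  sel <- gf$r > 20 & gf$r < 400
  expect_lt(max(abs(gf$g[sel] - gb$g[sel]) / gb$g[sel]), 0.02)
})

test_that("coincident points produce a short-range spike", {
  set.seed(63)
  base <- cbind(runif(200, 0, 1000), runif(200, 0, 1000))
  pts <- rbind(base, base + 1e-3)  # every point duplicated
  g <- pair_autocorrelation(pts, c(0, 1000, 0, 1000), r_max = 300,
                            bin_width = 10, grid = 5)
  expect_gt(g$g[1], 10 * mean(g$g[g$r > 100]))
})

test_that("cross-correlation is 1 for independent patterns and equals g for
           identical ones", {
  set.seed(64)
  pa <- cbind(runif(3000, 0, 2000), runif(3000, 0, 2000))
  pb <- cbind(runif(3000, 0, 2000), runif(3000, 0, 2000))
  cc <- pair_crosscorrelation(pa, pb, c(0, 2000, 0, 2000), r_max = 500)
  expect_lt(abs(mean(cc$g) - 1), 0.05)
  ## identical patterns: c(r) = g(r) apart from the self-pair bin
  g <- pair_autocorrelation(pa, c(0, 2000, 0, 2000), r_max = 500)
  cs <- pair_crosscorrelation(pa, pa, c(0, 2000, 0, 2000), r_max = 500)
  sel <- g$r > 20
  expect_equal(cs$g[sel], g$g[sel], tolerance = 0.02)
})

test_that("two-exponential fit handles flat and single-scale inputs", {
  r <- seq(5, 795, 10)
  ## g identically 1: both amplitudes collapse to ~0
  f0 <- fit_g_two_exponential(data.frame(r = r, g = rep(1, length(r))))
  expect_lt(f0$A1 + ifelse(is.na(f0$A2), 0, f0$A2), 0.05)
  ## exact single-scale curve: one amplitude vanishes or both share xi
  g1 <- 1 + 5 * exp(-r / 40)
  f1 <- fit_g_two_exponential(data.frame(r = r, g = g1))
  a_slow <- ifelse(is.na(f1$A2), 0, f1$A2)
  recovered <- abs(f1$xi1 - 40) < 4 || (a_slow > 0.1 && abs(f1$xi2 - 40) < 4)
  expect_true(recovered)
  ## exact two-scale curve: both lengths recovered
  g2 <- 1 + 8 * exp(-r / 25) + 0.8 * exp(-r / 150)
  f2 <- fit_g_two_exponential(data.frame(r = r, g = g2))
  expect_equal(f2$xi1, 25, tolerance = 0.05)
  expect_equal(f2$xi2, 150, tolerance = 0.05)
  expect_true(f2$xi1 < f2$xi2)
})

test_that("tail exponential fit recovers the printed closed form", {
  r <- seq(5, 795, 10)
  tf <- fit_c_tail_exponential(data.frame(r = r, g = 1 + exp(-r / 153)))
  expect_equal(tf$two_xi, 306, tolerance = 1e-3)
  ## flat tail is flagged
  expect_warning(
    tfp <- fit_c_tail_exponential(data.frame(r = r, g = rep(1, length(r)))),
    "flat")
  expect_true(tfp$flat_tail)
  expect_error(fit_c_tail_exponential(data.frame(r = r[r < 100],
                                                 g = rep(1, sum(r < 100)))),
               "beyond")
})

test_that("correlation averaging propagates mean and SEM", {
  r <- seq(5, 95, 10)
  c1 <- data.frame(r = r, g = rep(1, 10))
  c2 <- data.frame(r = r, g = rep(3, 10))
  av <- average_correlation(list(c1, c2))
  expect_equal(av$g, rep(2, 10))
  expect_equal(av$sem, rep(1, 10))
})
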