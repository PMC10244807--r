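test_that("stretched-exponential on-time fit recovers parameters", {
  set.seed(21)
  ## pure exponential special case (alpha = 1)
  f1 <- fit_stretched_exponential(nanofa:::rstretched_exp(6000, 2, 1),
                                  bin_width = 0.5)
  expect_equal(f1$alpha, 1, tolerance = 0.05)
  expect_equal(f1$tau, 2, tolerance = 0.1)
  ## stretched case: recovery within 3 fitted SEs
  f2 <- fit_stretched_exponential(nanofa:::rstretched_exp(5000, 2, 0.7),
                                  bin_width = 1)
  expect_lt(abs(f2$tau - 2), 3 * f2$se_tau + 0.2)
  expect_lt(abs(f2$alpha - 0.7), 3 * f2$se_alpha + 0.02)
  ## too few informative bins is refused
  expect_error(fit_stretched_exponential(rep(1.2, 500), bin_width = 1),
               "fewer than 4")
})

test_that("exponential photon fit returns the decay constant", {
  x <- seq(5, 500, 10)
  f49 <- fit_exponential_photons(data.frame(x = x, count = 1000 * exp(-x / 49)))
  expect_equal(f49$mean_photons, 49, tolerance = 1e-3)
  x2 <- seq(10, 3000, 50)
  f477 <- fit_exponential_photons(data.frame(x = x2,
                                             count = 500 * exp(-x2 / 477)))
  expect_equal(f477$mean_photons, 477, tolerance = 1e-3)
  ## flat histogram: poorly determined, must warn
  expect_warning(
    fit_exponential_photons(data.frame(x = seq(10, 100, 10),
                                       count = rep(100, 10))),
    "poorly determined")
})

test_that("geometric blinking fit matches the printed overcounting factors", {
  set.seed(22)
  n72 <- rgeom(100000, 0.72) + 1L
  g72 <- fit_geometric_blinking(n72)
  expect_equal(g72$mean_detections, 1 / 0.72, tolerance = 0.01)
  expect_equal(signif(g72$mean_detections, 2), 1.4)
  n37 <- rgeom(100000, 0.37) + 1L
  g37 <- fit_geometric_blinking(n37)
  expect_equal(signif(g37$mean_detections, 2), 2.7)
  ## exact identity p * mean_detections = 1
  expect_equal(g72$p * g72$mean_detections, 1)
  ## all singletons
  expect_equal(fit_geometric_blinking(rep(1L, 50))$p, 1)
  ## invalid counts rejected
  expect_error(fit_geometric_blinking(c(0, 1, 2)), "integers >= 1")
  expect_error(fit_geometric_blinking(c(1.5, 2)), "integers >= 1")
})

test_that("localization precision follows the closed-form limits", {
  ## F = 1, b = 0: sigma = sqrt(16/9) * sa / sqrt(N)
  sa <- sqrt(129^2 + 55.1^2 / 12)
  expect_equal(localization_precision(100, 129, 55.1, 0, 1),
               sqrt(16 / 9) * sa / sqrt(100))
  ## doubling photons with b = 0 shrinks sigma by sqrt(2)
  s1 <- localization_precision(100, background_var = 0)
  s2 <- localization_precision(200, background_var = 0)
  expect_equal(s1 / s2, sqrt(2))
  ## the mEos3.2 operating point: some plausible camera background
  ## variance yields the 29-nm precision at 49 photons
  bs <- seq(0, 3, by = 0.01)
  sig <- localization_precision(49, 129, 55.1, bs, 1.2)
  b_hit <- bs[which.min(abs(sig - 29))]
  expect_lt(abs(localization_precision(49, 129, 55.1, b_hit, 1.2) - 29), 0.5)
  expect_gt(b_hit, 0)      # a real, positive background level
  expect_lt(b_hit, 3)      # and a modest one (a few photons^2/pixel)
})

test_that("spot-survival curves normalize to 100% at time zero", {
  ## constant emitter population: flat at 100%
  lt <- loc_table(frame = rep(1:100, each = 5), x_nm = 0, y_nm = 0)
  sv <- spot_survival_curve(lt, window = 10)
  expect_true(all(sv$pct == 100))
  ## single frame of data: one point at 100%
  sv1 <- spot_survival_curve(loc_table(frame = rep(1L, 7), x_nm = 0, y_nm = 0))
  expect_equal(nrow(sv1), 1)
  expect_equal(sv1$pct, 100)
  ## per-frame bleaching of a finite pool: measured survival matches
  ## the analytic (1 - q)^t decay within 3 SE
  set.seed(23)
  n0 <- 5000; q <- 0.05; n_frames <- 40
  alive <- rep(TRUE, n0)
  frames <- integer(0)
  for (f in seq_len(n_frames)) {
    frames <- c(frames, rep(f, sum(alive)))
    alive[alive] <- runif(sum(alive)) > q
  }
  sv2 <- spot_survival_curve(loc_table(frame = frames, x_nm = 0, y_nm = 0),
                             window = 1)
  t_mid <- 20
  expected <- 100 * (1 - q)^(t_mid - 1)
  se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / n0)
  expect_lt(abs(sv2$pct[t_mid] - expected), 3 * se + 1)
})
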