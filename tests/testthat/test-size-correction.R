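# Scaled-down checks of the Monte-Carlo size-correction machinery; the
# full-scale rebuild at the published settings lives in the acceptance
# suite.

test_that("calibration curves are monotone and ordered by blur", {
  grid <- c(40, 70, 100)
  cv0 <- build_calibration(0, 1.4, d_true_grid = grid, n_images = 8,
                           seed = 51)
  cv29 <- build_calibration(29, 1.4, d_true_grid = grid, n_images = 8,
                            seed = 52)
  ## monotone increasing in d_true
  expect_true(all(diff(cv0$table$d_est_mean) > 0))
  expect_true(all(diff(cv29$table$d_est_mean) > 0))
  ## blur inflates the estimate at every grid point (within 2 SEM)
  tol <- 2 * sqrt(cv0$table$d_est_sem^2 + cv29$table$d_est_sem^2)
  expect_true(all(cv29$table$d_est_mean - cv0$table$d_est_mean > -tol))
  ## zero-error curve stays near the identity line
  expect_true(all(abs(cv0$table$d_est_mean - grid) / grid < 0.15))
  ## fixed seed reproduces the curve exactly
  cv0b <- build_calibration(0, 1.4, d_true_grid = grid, n_images = 8,
                            seed = 51)
  expect_identical(cv0$table, cv0b$table)
})

test_that("diameter correction inverts the fitted quadratic", {
  ## synthetic curve with known coefficients
  cv <- structure(list(coeffs = c(30, 0.8, 0.002), valid_range = c(20, 120)),
                  class = "calibration_curve")
  d_est <- predict_d_est(cv, c(30, 60, 90))
  expect_equal(correct_diameter(d_est, cv), c(30, 60, 90), tolerance = 1e-8)
  ## values mapping below the physical floor are clipped with a warning
  expect_warning(out <- correct_diameter(5, cv), "clipping")
  expect_equal(out, 5)
  ## near-linear curve falls back to linear inversion
  cvl <- structure(list(coeffs = c(10, 1, 0), valid_range = c(20, 120)),
                   class = "calibration_curve")
  expect_equal(correct_diameter(70, cvl), 60)
})

test_that("closeness metric is zero for a perfect estimator and
           selects from a single candidate trivially", {
  sel1 <- select_density_factor(1.45, seed = 53, n_images = 2)
  expect_equal(sel1$factor, 1.45)
  ## metric formula check on a fabricated perfect table
  tab <- data.frame(d_true = seq(30, 100, 10),
                    d_est_mean = seq(30, 100, 10))
  expect_equal(sum((tab$d_est_mean - tab$d_true)^2 / tab$d_true^2), 0)
})

test_that("large islands are nearly always detectable", {
  det <- detectability(120, 29, n_images = 10, seed = 54)
  expect_gte(det, 0.85)
})

test_that("truth-island matching picks the best local object", {
  isl <- data.frame(object = 1:3, cx = c(100, 112, 500),
                    cy = c(100, 100, 500), n_locs = c(20, 8, 15),
                    diameter = c(40, 15, 60))
  truth <- data.frame(x = c(105, 800), y = c(100, 800))
  dm <- match_island_diameters(isl, truth, r_match = 50)
  expect_equal(dm, c(40, NA))
})
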