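test_that("immobilization detection finds stationary stretches", {
  set.seed(91)
  ## pure noise around a fixed point: one event spanning all frames
  tr <- data.frame(frame = 1:48, x_nm = rnorm(48, 0, 21),
                   y_nm = rnorm(48, 0, 21))
  ev <- detect_immobilization(tr, loc_sigma = 21, min_duration_frames = 15,
                              frame_time = 4)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 1)
  expect_equal(ev$end_frame, 48)
  ## circle diameter ~ 2 (Rg + sigma): near the 104-nm scale at 21 nm
  expect_gt(ev$circle_diameter, 60)
  expect_lt(ev$circle_diameter, 130)

  ## immobile - mobile - immobile gives two events
  mob <- data.frame(frame = 49:98,
                    x_nm = cumsum(rnorm(50, 0, 60)) + 200,
                    y_nm = cumsum(rnorm(50, 0, 60)))
  tr3 <- rbind(tr, mob,
               data.frame(frame = 99:146,
                          x_nm = rnorm(48, 2000, 21),
                          y_nm = rnorm(48, 2000, 21)))
  ev3 <- detect_immobilization(tr3, 21, 15, frame_time = 4)
  expect_equal(nrow(ev3), 2)
  expect_error(detect_immobilization(tr, 0, 15), "positive")
})

test_that("free diffusion rarely triggers immobilization events", {
  ## D = 0.1 um^2/s at 250 Hz, event duration at the published ~0.2-s
  ## scale: false-positive rate below 5%
  set.seed(92)
  st <- sqrt(2 * 100 * 4)   # nm per 4-ms frame at 100 nm^2/ms
  n_ev <- vapply(1:40, function(i) {
    tr <- data.frame(frame = 1:250, x_nm = cumsum(rnorm(250, 0, st)),
                     y_nm = cumsum(rnorm(250, 0, st)))
    nrow(detect_immobilization(tr, 21, 48, frame_time = 4))
  }, numeric(1))
  expect_lt(mean(n_ev > 0), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})

test_that("thermographic normalization divides by the masked median", {
  img <- matrix(2, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  nm <- thermographic_normalize(img, mask)
  expect_true(all(nm == 1))
  expect_equal(attr(nm, "clip_range"), c(0, 6))
  img2 <- matrix(c(rep(2, 50), rep(6, 50)), 10, 10)
  nm2 <- thermographic_normalize(img2, mask)
  expect_equal(sort(unique(as.vector(nm2))), c(0.5, 1.5))
  expect_error(thermographic_normalize(matrix(0, 5, 5), matrix(TRUE, 5, 5)),
               "zero median")
})

test_that("intensity sampling reports the fraction in enriched territory", {
  ## synthetic map: left half below median-normalized 1, right half above
  nm <- matrix(rep(c(0.4, 1.6), each = 50), 10, 10)
  attr(nm, "pixel") <- 10
  attr(nm, "xlim") <- c(0, 100)
  attr(nm, "ylim") <- c(0, 100)
  ## events only on the enriched side
  ev_hi <- data.frame(cx = rep(75, 5), cy = seq(10, 90, 20),
                      circle_diameter = 20)
  out <- intensity_at_sites(nm, ev_hi)
  expect_equal(out$fraction_above_1, 1)
  ## events outside the map are skipped with a notice
  ev_out <- rbind(ev_hi, data.frame(cx = 500, cy = 500, circle_diameter = 20))
  expect_message(out2 <- intensity_at_sites(nm, ev_out), "skipped")
  expect_equal(out2$n_skipped, 1)
  expect_length(out2$values, 5)
})

test_that("CSR event placement yields an unbiased fraction above median", {
  ## property: ~0.5 within 3 SE over replicates
  set.seed(93)
  fracs <- vapply(1:100, function(i) {
    img <- matrix(runif(400), 20, 20)
    nm <- thermographic_normalize(img, matrix(TRUE, 20, 20))
    attr(nm, "pixel") <- 10; attr(nm, "xlim") <- c(0, 200)
    attr(nm, "ylim") <- c(0, 200)
    ev <- data.frame(cx = runif(20, 0, 200), cy = runif(20, 0, 200),
                     circle_diameter = 20)
    intensity_at_sites(nm, ev)$fraction_above_1
  }, numeric(1))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.5), 3 * se + 0.01)
})
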