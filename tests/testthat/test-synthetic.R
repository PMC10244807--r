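test_that("generators are reproducible under a fixed seed", {
  s1 <- generate_fa_scene(scene_config(seed = 42))
  s2 <- generate_fa_scene(scene_config(seed = 42))
  expect_identical(s1$molecules, s2$molecules)
  expect_identical(s1$islands, s2$islands)

  f1 <- simulate_calibration_field(60, 29, 1.4, n_images = 2, seed = 7)
  f2 <- simulate_calibration_field(60, 29, 1.4, n_images = 2, seed = 7)
  expect_identical(f1, f2)

  t1 <- simulate_hop_trajectory(hop_sim_config(seed = 3, n_steps = 50))
  t2 <- simulate_hop_trajectory(hop_sim_config(seed = 3, n_steps = 50))
  expect_identical(t1$x_nm, t2$x_nm)
})

test_that("scene geometry honors its invariants", {
  cfg <- scene_config(seed = 1, islands_per_cluster = 4, n_clusters = 3)
  sc <- generate_fa_scene(cfg)
  ## every island disk lies inside the FA polygon
  poly <- cfg$fa_polygon
  for (i in seq_len(nrow(sc$islands))) {
    th <- seq(0, 2 * pi, length.out = 12)
    expect_true(all(pracma::inpolygon(
      sc$islands$x[i] + sc$islands$d_true[i] / 2 * cos(th),
      sc$islands$y[i] + sc$islands$d_true[i] / 2 * sin(th),
      poly$x, poly$y)))
  }
  ## no islands requested -> pure background
  sc0 <- generate_fa_scene(scene_config(seed = 2, islands_per_cluster = 0))
  expect_true(all(sc0$molecules$island_id <= 0))
  ## negative diameters are rejected
  bad <- scene_config(seed = 3, island_diameter_law = function(n) rep(-5, n))
  expect_error(generate_fa_scene(bad), "negative")
  ## min_island_gap is respected
  scg <- generate_fa_scene(scene_config(seed = 4, min_island_gap = 150,
                                        islands_per_cluster = 3,
                                        cluster_diameter = 400))
  dmat <- as.matrix(dist(scg$islands[, c("x", "y")]))
  expect_true(min(dmat[upper.tri(dmat)]) >= 150)
})

test_that("calibration fields have the prescribed geometry and density", {
  ## side length is 10x the diameter, 20x for the 20-nm case
  f20 <- simulate_calibration_field(20, 0, 1, n_images = 1, seed = 1)
  expect_equal(attr(f20[[1]], "side"), 400)
  f60 <- simulate_calibration_field(60, 0, 1, n_images = 30, seed = 2)
  expect_length(f60, 30)
  expect_equal(attr(f60[[1]], "side"), 600)
  ## expected in-island spot count = density x area (sigma 0, no blinking)
  n_in <- vapply(f60, function(f) sum(f$in_island), numeric(1))
  expect_equal(mean(n_in), 0.02 * pi * 30^2, tolerance = 0.1)
  expect_error(simulate_calibration_field(60, 0, 1, n_images = 0), "n_images")
})

test_that("localization counts follow area x density x overcount x fluorescence", {
  ## law-of-large-numbers check over replicates
  set.seed(11)
  area <- 4e6
  mol_density <- 5e-4
  ph <- photophysics_config(p_bleach = 1 / 1.4, fluorescent_fraction = 0.6,
                            on_time_tau = 0.05, loc_sigma = 0)
  counts <- replicate(50, {
    n <- rpois(1, mol_density * area)
    mol <- data.frame(x = runif(n, 0, 2000), y = runif(n, 0, 2000))
    lt <- simulate_blinking(mol, ph, n_frames = 5000)
    length(unique(lt$event_id))
  })
  expected <- area * mol_density * 1.4 * 0.6
  expect_equal(mean(counts), expected, tolerance = 0.05)
})

test_that("blinking special cases behave", {
  mol <- data.frame(x = rep(0, 500), y = rep(0, 500))
  ## p_bleach = 1: exactly one on-event per fluorescent molecule
  ph1 <- photophysics_config(p_bleach = 1, fluorescent_fraction = 1,
                             on_time_tau = 0.5, loc_sigma = 0)
  lt <- simulate_blinking(mol, ph1, 1000, seed = 5)
  expect_equal(length(unique(lt$event_id)), 500)
  ## fluorescent_fraction thins molecules binomially
  ph2 <- photophysics_config(p_bleach = 1, fluorescent_fraction = 0.6,
                             on_time_tau = 0.5, loc_sigma = 0)
  n_emit <- replicate(30, {
    length(unique(simulate_blinking(mol, ph2, 1000)$molecule_id))
  })
  expect_equal(mean(n_emit), 300, tolerance = 3 * sqrt(500 * .6 * .4 / 30) / 300)
  ## empirical mean on-events at p = 0.72 is ~1.39
  ph3 <- photophysics_config(p_bleach = 0.72, fluorescent_fraction = 1,
                             on_time_tau = 0.5, loc_sigma = 0)
  big <- data.frame(x = rep(0, 20000), y = rep(0, 20000))
  lt3 <- simulate_blinking(big, ph3, 1000, seed = 6)
  expect_equal(length(unique(lt3$event_id)) / 20000, 1 / 0.72,
               tolerance = 0.02)
})

test_that("hop simulator reproduces the free and confined limits", {
  ## free Brownian: MSD slope 4 D within 3 SE over 100 trajectories
  D <- 5
  slopes <- vapply(1:100, function(i) {
    tr <- simulate_hop_trajectory(hop_sim_config(109, D, 1, n_steps = 200,
                                                 seed = 100 + i))
    m <- compute_msd(tr)
    unname(coef(lm(msd ~ dt_ms, data = m[1:10, ]))[2]) / 4 / 1000
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - D), 3 * se)

  ## full confinement: MSD plateaus near L^2/3
  tr0 <- simulate_hop_trajectory(hop_sim_config(100, 5, 0, n_steps = 1500,
                                                seed = 9))
  m0 <- compute_msd(tr0)
  plateau <- mean(tail(m0$msd, 100))
  expect_equal(plateau, 100^2 / 3, tolerance = 0.10)
})

test_that("hop probability calibration hits a target residency time", {
  hp <- hop_probability_for_tau(109, 5, 24, seed = 3)
  dw <- unlist(lapply(1:15, function(i)
    attr(simulate_hop_trajectory(hop_sim_config(109, 5, hp, n_steps = 1500,
                                                seed = 200 + i)),
         "dwell_ms")))
  ## completed dwells on 250-ms trajectories are length-biased; the
  ## window-corrected lifetime fit recovers the target
  tau_hat <- fit_residency_times(dw, frame_time = 1 / 6,
                                 window_ms = 250)$tau
  expect_equal(tau_hat, 24, tolerance = 0.10)
})

test_that("localization tables round-trip through CSV", {
  lt <- loc_table(frame = 1:3, x_nm = c(1.5, 2, 3), y_nm = c(4, 5, 6.25),
                  photons = c(10, 20, 30), uncertainty_nm = 29,
                  molecule_id = c(1L, 1L, 2L))
  p <- tempfile(fileext = ".csv")
  write_localizations(lt, p)
  back <- read_localizations(p)
  expect_equal(back$x_nm, lt$x_nm)
  expect_equal(back$molecule_id, lt$molecule_id)
  tr <- data.frame(frame = 1:5, x_nm = rnorm(5), y_nm = rnorm(5))
  p2 <- tempfile(fileext = ".csv")
  write_trajectory(tr, p2)
  expect_equal(read_trajectory(p2)$y_nm, tr$y_nm)
})
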