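test_that("merge cutoff distance reproduces both printed values", {
  expect_equal(merge_cutoff_distance(29, 2), 82)
  expect_equal(merge_cutoff_distance(19, 3), 81)
  ## linear in sigma
  expect_equal(merge_cutoff_distance(58, 2), 2 * merge_cutoff_distance(29, 2))
  expect_error(merge_cutoff_distance(29, 4))
})

test_that("gap closing merges same-emitter localizations and is idempotent", {
  cfg <- merge_config(max_off_frames = 1, max_distance = 82)
  ## two spots 10 nm apart in consecutive frames -> one on-event
  lt <- loc_table(frame = c(1L, 2L), x_nm = c(0, 10), y_nm = c(0, 0),
                  photons = c(30, 10))
  m <- gap_close_and_merge(lt, cfg)
  expect_equal(nrow(m), 1)
  expect_equal(m$x_nm, (30 * 0 + 10 * 10) / 40)  # photon-weighted mean
  expect_equal(m$photons, 40)
  ## 200 nm apart -> two on-events
  lt2 <- loc_table(frame = c(1L, 2L), x_nm = c(0, 200), y_nm = c(0, 0))
  expect_equal(nrow(gap_close_and_merge(lt2, cfg)), 2)
  ## a 2-frame dark gap is not bridged at max_off_frames = 1
  lt3 <- loc_table(frame = c(1L, 4L), x_nm = c(0, 5), y_nm = c(0, 0))
  expect_equal(nrow(gap_close_and_merge(lt3, cfg)), 2)
  ## unsorted input is sorted with a warning
  expect_warning(gap_close_and_merge(lt[2:1, ], cfg), "sort")

  ## idempotence on a sparse table (emitters far apart relative to the
  ## cutoff, so no pair sits on the decision boundary)
  lt4 <- make_sparse_blink_table(31, n_mol = 100, field = 4e4, sigma = 2)
  m4 <- gap_close_and_merge(lt4, cfg)
  m5 <- gap_close_and_merge(m4, cfg)
  expect_equal(nrow(m5), nrow(m4))
  expect_equal(m4$x_nm, m5$x_nm)
})

test_that("merged on-event count matches generator truth within 2%", {
  ## sparse field, noise well below the cutoff so no events split
  set.seed(32)
  mol <- data.frame(x = runif(300, 0, 3e4), y = runif(300, 0, 3e4))
  ph <- photophysics_config(p_bleach = 0.72, fluorescent_fraction = 1,
                            loc_sigma = 2)
  lt <- simulate_blinking(mol, ph, 10000, seed = 33)
  truth <- length(unique(lt$event_id))
  m <- gap_close_and_merge(lt, merge_config(1, 82))
  expect_equal(nrow(m), truth, tolerance = 0.02)
})

test_that("molecule grouping counts on-events per molecule", {
  cfg <- merge_config(max_off_frames = 1, max_distance = 82, cutoff_time = 3)
  ## three well-separated on-events of one molecule within 3 s -> N = 3
  ev <- loc_table(frame = c(100L, 900L, 2500L), x_nm = c(0, 20, 10),
                  y_nm = c(0, 5, 15))
  g <- group_molecule_detections(ev, cfg, frame_time = 1)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_detections, 3L)
  ## events 5 s apart at the 3-s cutoff -> two molecules
  ev2 <- loc_table(frame = c(100L, 5100L), x_nm = c(0, 10), y_nm = c(0, 0))
  expect_equal(nrow(group_molecule_detections(ev2, cfg, frame_time = 1)), 2)
  ## sparse simulation: recovered mean N within 5% of the generator
  ## mean (the time cutoff must cover the acquisition, because the
  ## generator spreads a molecule's on-events uniformly over it)
  cfg10 <- merge_config(max_off_frames = 1, max_distance = 82,
                        cutoff_time = 10)
  lt <- make_sparse_blink_table(34, n_mol = 300, field = 3e4, sigma = 5)
  m <- gap_close_and_merge(lt, cfg10)
  g3 <- group_molecule_detections(m, cfg10, frame_time = 1)
  truth_mean <- nrow(m) / length(unique(m$molecule_id))
  expect_equal(mean(g3$n_detections), truth_mean, tolerance = 0.05)
})

test_that("Gaussian rendering conserves intensity", {
  lt <- loc_table(frame = 1L, x_nm = 500, y_nm = 400)
  img <- render(lt, pixel = 10, sigma = 29)
  expect_equal(sum(img), 1, tolerance = 1e-3)
  ## two coincident localizations double the peak
  lt2 <- loc_table(frame = c(1L, 2L), x_nm = c(500, 500), y_nm = c(400, 400))
  img2 <- render(lt2, pixel = 10, sigma = 29,
                 xlim = attr(img, "xlim"), ylim = attr(img, "ylim"))
  expect_equal(max(img2), 2 * max(img), tolerance = 1e-6)
  ## aliasing warning when sigma < pixel/2
  expect_warning(render(lt, pixel = 55.1, sigma = 20), "alias")
  ## many localizations still sum to n
  set.seed(35)
  ltn <- loc_table(frame = 1:200, x_nm = runif(200, 0, 2000),
                   y_nm = runif(200, 0, 2000))
  expect_equal(sum(render(ltn, pixel = 10, sigma = 29)), 200,
               tolerance = 1e-3)
})

test_that("sliding-window reconstruction produces the expected frame count", {
  set.seed(36)
  lt <- loc_table(frame = c(1L, 60000L, sample.int(60000, 4998)),
                  x_nm = runif(5000, 0, 1000),
                  y_nm = runif(5000, 0, 1000))
  ## 60-s acquisition at 1 kHz, 10-s window, 1-s step -> 51 frames
  sw <- sliding_window_reconstruction(lt, window = 10, step = 1,
                                      frame_time = 1, pixel = 50, sigma = 50)
  expect_equal(length(sw$images), 51)
  ## step = window tiles without overlap
  sw2 <- sliding_window_reconstruction(lt, window = 10, step = 10,
                                       frame_time = 1, pixel = 50, sigma = 50)
  expect_equal(length(sw2$images), 6)
  expect_error(sliding_window_reconstruction(lt, window = 100, step = 1,
                                             frame_time = 1), "window")
})

test_that("recruitment time-courses report per-circle percentages", {
  poly <- list(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000))
  circ <- data.frame(x = c(250, 750), y = c(500, 500), diameter = 250)
  ## all localizations in circle 1 -> 100% there, 0% elsewhere
  lt <- loc_table(frame = 1:100, x_nm = rnorm(100, 250, 20),
                  y_nm = rnorm(100, 500, 20))
  rc <- recruitment_timecourse(lt, circ, poly, window = 10, frame_time = 100)
  expect_true(all(rc$pct[rc$circle == 1] == 100))
  expect_true(all(rc$pct[rc$circle == 2] == 0))
  ## uniform CSR: percentage ~ circle area / FA area
  set.seed(37)
  lt2 <- loc_table(frame = rep(1L, 20000), x_nm = runif(20000, 0, 1000),
                   y_nm = runif(20000, 0, 1000))
  rc2 <- recruitment_timecourse(lt2, circ, poly, window = 10,
                                frame_time = 100)
  expect_equal(rc2$pct[1] / 100, pi * 125^2 / 1e6, tolerance = 0.1)
})
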