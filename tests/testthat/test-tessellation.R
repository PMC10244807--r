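test_that("clipped Voronoi polygons partition the ROI", {
  set.seed(41)
  lt <- loc_table(frame = 1:500, x_nm = runif(500, 0, 1000),
                  y_nm = runif(500, 0, 800))
  vd <- voronoi_densities(lt, roi = c(0, 1000, 0, 800))
  expect_equal(sum(vd$area), 1000 * 800, tolerance = 1e-6)
  ## CSR: mean rank-0 density of the cells is near N / A
  vd0 <- voronoi_densities(lt, roi = c(0, 1000, 0, 800), neighbor_rank = 0)
  expect_equal(mean(1 / vd0$area) > 500 / 8e5, TRUE)  # Jensen direction
  expect_equal(sum(vd0$area), 8e5, tolerance = 1e-6)
})

test_that("four symmetric points get equal densities", {
  lt <- loc_table(frame = 1:4, x_nm = c(0.25, 0.75, 0.25, 0.75),
                  y_nm = c(0.25, 0.25, 0.75, 0.75))
  vd <- voronoi_densities(lt, roi = c(0, 1, 0, 1), neighbor_rank = 0)
  expect_equal(vd$area, rep(0.25, 4))
  expect_equal(vd$density, rep(4, 4))
})

test_that("degenerate geometry still yields a valid partition", {
  ## exactly collinear sites plus exact duplicates
  lt <- loc_table(frame = 1:6, x_nm = c(10, 20, 30, 10, 20, 30),
                  y_nm = rep(5, 6))
  vd <- suppressWarnings(voronoi_densities(lt, roi = c(0, 40, 0, 10)))
  expect_equal(sum(vd$area), 400, tolerance = 1e-6)
  expect_true(all(is.finite(vd$density)))
})

test_that("object detection enforces the island definition", {
  set.seed(42)
  ## a dense blob of 5 localizations only: rejected at min_locs = 6
  blob5 <- cbind(rnorm(5, 500, 5), rnorm(5, 500, 5))
  bg <- cbind(runif(200, 0, 1000), runif(200, 0, 1000))
  lt <- loc_table(frame = seq_len(205), x_nm = c(blob5[, 1], bg[, 1]),
                  y_nm = c(blob5[, 2], bg[, 2]))
  vd <- voronoi_densities(lt, roi = c(0, 1000, 0, 1000))
  obj5 <- detect_objects(vd, 1.45 * mean(vd$density), min_diameter = 13,
                         min_locs = 6)
  near5 <- obj5[abs(obj5$cx - 500) < 30 & abs(obj5$cy - 500) < 30, ]
  expect_equal(nrow(near5), 0)
  ## the same blob with 8 localizations is accepted
  blob8 <- cbind(rnorm(8, 500, 5), rnorm(8, 500, 5))
  lt8 <- loc_table(frame = seq_len(208), x_nm = c(blob8[, 1], bg[, 1]),
                   y_nm = c(blob8[, 2], bg[, 2]))
  vd8 <- voronoi_densities(lt8, roi = c(0, 1000, 0, 1000))
  obj8 <- detect_objects(vd8, 1.45 * mean(vd8$density), 13, 6)
  near8 <- obj8[abs(obj8$cx - 500) < 30 & abs(obj8$cy - 500) < 30, ]
  expect_gte(nrow(near8), 1)
  ## diameter definition d = 2 sqrt(A / pi) holds for every record
  expect_equal(obj8$diameter, 2 * sqrt(obj8$area / pi))
})

test_that("raising the density factor never grows an object", {
  f <- simulate_calibration_field(60, 0, 1.4, n_images = 1, seed = 43)[[1]]
  side <- attr(f, "side")
  vd <- voronoi_densities(f, roi = c(0, side, 0, side))
  base <- mean(vd$density)
  a_prev <- Inf
  for (fac in c(1.2, 1.45, 2.0)) {
    obj <- detect_objects(vd, fac * base, 13, 6)
    ctr <- obj[(obj$cx - side / 2)^2 + (obj$cy - side / 2)^2 < 60^2, ]
    a_now <- if (nrow(ctr)) max(ctr$area) else 0
    expect_lte(a_now, a_prev + 1e-9)
    a_prev <- a_now
  }
})

test_that("two-pass segmentation nests islands inside their FA", {
  scn <- generate_fa_scene(scene_config(seed = 44, n_clusters = 2,
                                        islands_per_cluster = 4,
                                        min_island_gap = 150,
                                        cluster_diameter = 400))
  ph <- photophysics_config(on_time_tau = 0.05, fluorescent_fraction = 1,
                            loc_sigma = 29)
  lt <- simulate_blinking(scn$molecules, ph, 10000, seed = 45)
  seg <- segment_fa_and_islands(lt, roi = scn$roi)
  expect_gte(nrow(seg$fa), 1)
  expect_false(is.null(seg$islands))
  ## nesting: every island's members are a subset of its parent FA's
  for (i in seq_len(nrow(seg$islands))) {
    fa_mem <- seg$fa$members[[which(seg$fa$object == seg$islands$fa_id[i])]]
    expect_true(all(seg$islands$members[[i]] %in% fa_mem))
  }
  ## FA minimum size: every FA at least the 178-nm-circle area
  expect_true(all(seg$fa$area >= pi * (178 / 2)^2))
  ## a perfectly uniform field has no polygon above 1.45x the mean:
  ## empty result with a notice
  gr <- expand.grid(x = seq(250, 4750, 500), y = seq(250, 4750, 500))
  uniform <- loc_table(frame = seq_len(nrow(gr)), x_nm = gr$x,
                       y_nm = gr$y)
  expect_message(
    seg0 <- segment_fa_and_islands(uniform, roi = c(0, 5000, 0, 5000)),
    "no FA")
  expect_equal(nrow(seg0$fa), 0)
})

test_that("object outline polygons cover the member area", {
  set.seed(46)
  blob <- cbind(rnorm(30, 300, 15), rnorm(30, 300, 15))
  bg <- cbind(runif(100, 0, 600), runif(100, 0, 600))
  lt <- loc_table(frame = 1:130, x_nm = c(blob[, 1], bg[, 1]),
                  y_nm = c(blob[, 2], bg[, 2]))
  vd <- voronoi_densities(lt, roi = c(0, 600, 0, 600))
  obj <- detect_objects(vd, 1.45 * mean(vd$density), 13, 6)
  stopifnot(nrow(obj) >= 1)
  poly <- object_polygon(vd, obj$members[[1]])
  expect_gt(abs(pracma::polyarea(poly$x, poly$y)), 0)
})

test_that("binarization splits two-level and flags constant images", {
  img <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  m <- binarize_image(img, "min_cross_entropy")
  expect_identical(m, img > 0.5)
  expect_warning(binarize_image(matrix(1, 5, 5)), "constant")
  ## Sauvola covers most of a bright synthetic FA on dark background
  set.seed(47)
  fa <- matrix(0, 120, 120)
  fa[40:80, 30:90] <- 1
  img2 <- fa + matrix(runif(120 * 120, 0, 0.05), 120)
  m2 <- binarize_image(img2, "sauvola", radius = 30, k = 0.2, r = 0.5)
  expect_gt(mean(m2[40:80, 30:90]), 0.9)
  m3 <- binarize_image(img2, "min_cross_entropy")
  expect_gt(mean(m3[40:80, 30:90]), 0.9)
  expect_lt(mean(m3[1:30, 1:20]), 0.1)
})
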