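# Shared fixtures, all generated in code at test time.

# point pattern of circular islands grouped in loose clusters, with
# optional Gaussian localization blur
make_cluster_pattern <- function(seed, d_island = 60, sigma = 0,
                                 field = 6000, n_clusters = 25,
                                 islands_per_cluster = 6,
                                 cluster_radius = 150,
                                 locs_per_island = 25) {
  set.seed(seed)
  ccx <- runif(n_clusters, 300, field - 300)
  ccy <- runif(n_clusters, 300, field - 300)
  xs <- ys <- numeric(0)
  for (ci in seq_len(n_clusters)) for (k in seq_len(islands_per_cluster)) {
    a <- runif(1, 0, 2 * pi); rr <- cluster_radius * sqrt(runif(1))
    ix <- ccx[ci] + rr * cos(a); iy <- ccy[ci] + rr * sin(a)
    n <- rpois(1, locs_per_island)
    if (n > 0) {
      aa <- runif(n, 0, 2 * pi); r2 <- d_island / 2 * sqrt(runif(n))
      xs <- c(xs, ix + r2 * cos(aa) + rnorm(n, 0, sigma))
      ys <- c(ys, iy + r2 * sin(aa) + rnorm(n, 0, sigma))
    }
  }
  keep <- xs > 0 & xs < field & ys > 0 & ys < field
  cbind(xs[keep], ys[keep])
}

# independent pair-correlation oracle: direct pair counting
# (spatstat.geom::closepairs) normalized by the analytic isotropic set
# covariance of the rectangular window -- no FFT involved
oracle_autocorrelation <- function(xy, field_w, field_h, r_max, bin_width) {
  pp <- spatstat.geom::ppp(xy[, 1], xy[, 2],
                           window = spatstat.geom::owin(c(0, field_w),
                                                        c(0, field_h)))
  cp <- spatstat.geom::closepairs(pp, rmax = r_max, what = "indices",
                                  twice = TRUE)
  d <- sqrt((xy[cp$i, 1] - xy[cp$j, 1])^2 + (xy[cp$i, 2] - xy[cp$j, 2])^2)
  counts <- hist(d, breaks = seq(0, r_max, bin_width), plot = FALSE)$counts
  rho2 <- (nrow(xy) / (field_w * field_h))^2
  expected <- vapply(seq_along(counts), function(k) {
    f <- function(r) vapply(r, function(rr) {
      th <- seq(0, 2 * pi, length.out = 361)[-361]
      mean(pmax(field_w - abs(rr * cos(th)), 0) *
             pmax(field_h - abs(rr * sin(th)), 0)) * 2 * pi * rr
    }, numeric(1))
    stats::integrate(f, (k - 1) * bin_width, k * bin_width,
                     subdivisions = 50)$value * rho2
  }, numeric(1))
  data.frame(r = (seq_along(counts) - 0.5) * bin_width,
             g = counts / expected)
}

# quick sparse-molecule blinking table for merge/grouping tests
make_sparse_blink_table <- function(seed, n_mol = 200, field = 20000,
                                    p_bleach = 0.72, sigma = 5,
                                    n_frames = 10000) {
  set.seed(seed)
  mol <- data.frame(x = runif(n_mol, 0, field), y = runif(n_mol, 0, field))
  ph <- photophysics_config(p_bleach = p_bleach, fluorescent_fraction = 1,
                            loc_sigma = sigma)
  simulate_blinking(mol, ph, n_frames, seed = seed + 1)
}
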