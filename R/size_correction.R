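## Monte-Carlo calibration of the tessellation size estimate: finite
## localization precision and blinking inflate the apparent diameter of
## a circular island; simulating single-island fields across a grid of
## true diameters yields an invertible estimated-vs-true curve.

## run the island detector on one calibration field and return the
## central island's estimated diameter (NA if undetected).  The central
## island is the detected object whose centroid overlaps the true
## island footprint (its radius plus twice the localization error);
## fields whose only detections lie elsewhere count as misses.
measure_central_island <- function(field, density_factor, min_diameter = 13,
                                   min_locs = 6, neighbor_rank = 1) {
  side <- attr(field, "side")
  ctr <- attr(field, "center")
  d_true <- attr(field, "d_true")
  sigma <- field$uncertainty_nm[1]
  if (is.na(sigma)) sigma <- 0
  vd <- voronoi_densities(field, roi = c(0, side, 0, side),
                          neighbor_rank = neighbor_rank)
  rho <- mean(vd$density)
  obj <- detect_objects(vd, density_factor * rho,
                        min_diameter = min_diameter, min_locs = min_locs)
  if (nrow(obj) == 0) return(NA_real_)
  r_match <- d_true / 2 + 2 * sigma + 10
  d2 <- (obj$cx - ctr[1])^2 + (obj$cy - ctr[2])^2
  hit <- which(d2 <= r_match^2)
  if (!length(hit)) return(NA_real_)
  obj$diameter[hit[which.max(obj$n_locs[hit])]]
}

#' Build the Monte-Carlo size-correction calibration
#'
#' For each true diameter on the grid, simulates `n_images` single-island
#' fields ([simulate_calibration_field()]), detects the central island by
#' the Voronoi tessellation (density factor applied to the field mean
#' density, minimum diameter 13 nm) and records the mean estimated
#' diameter; a quadratic `d_est(d_true)` is fitted over
#' `d_true >= 20` nm.
#'
#' @param loc_sigma localization SD (nm): 29 for PALM/mEos3.2, 19 for
#'   dSTORM/HMSiR, 0 for the ideal reference.
#' @param overcount_mean mean on-events per molecule.
#' @param d_true_grid true diameters (nm), default 20-120 by 10.
#' @param n_images replicate fields per grid point (30).
#' @param density_factor Voronoi threshold factor (1.45).
#' @param min_locs island minimum localization count used during
#'   calibration detection (6).
#' @param neighbor_rank density averaging rank (1; must match the
#'   setting used for measurement).
#' @param seed integer seed.
#' @param island_spot_density,background_spot_density spot densities
#'   (0.02 / 0.002 per nm^2).
#' @return object of class `calibration_curve`: `table` (d_true,
#'   mean/SEM of d_est, detection fraction), `coeffs` (c0, c1, c2),
#'   `valid_range`, plus the generating parameters.
#' @export
build_calibration <- function(loc_sigma, overcount_mean,
                              d_true_grid = seq(20, 120, by = 10),
                              n_images = 30, density_factor = 1.45,
                              min_locs = 6, neighbor_rank = 1,
                              seed = NULL,
                              island_spot_density = 0.02,
                              background_spot_density = 0.002) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(d_true_grid, function(d) {
    fields <- simulate_calibration_field(
      d, loc_sigma, overcount_mean, n_images,
      island_spot_density = island_spot_density,
      background_spot_density = background_spot_density)
    d_est <- vapply(fields, measure_central_island, numeric(1),
                    density_factor = density_factor,
                    min_locs = min_locs, neighbor_rank = neighbor_rank)
    det <- mean(!is.na(d_est))
    if (loc_sigma > 0 && d >= 40 && det == 0)
      warning("no detections at d_true = ", d,
              " nm; expected detectability >= 85% at this size")
    data.frame(d_true = d, d_est_mean = mean(d_est, na.rm = TRUE),
               d_est_sem = sd(d_est, na.rm = TRUE) /
                 sqrt(max(1, sum(!is.na(d_est)))),
               detect_fraction = det, n_detected = sum(!is.na(d_est)))
  })
  tab <- do.call(rbind, rows)
  ## grid points where a sizable fraction of replicates yield no
  ## detection measure a selection-biased conditional mean (detected
  ## fields are the upward fluctuations), which flattens the low end
  ## and breaks the monotonicity the fitted curve must have; the
  ## quadratic is therefore fitted on the reliably detected points
  ## (detection fraction >= 0.9) and extrapolated below
  fitdat <- tab[tab$d_true >= 20 & is.finite(tab$d_est_mean) &
                  tab$detect_fraction >= 0.9, ]
  if (nrow(fitdat) < 4)
    fitdat <- tab[tab$d_true >= 20 & is.finite(tab$d_est_mean), ]
  w <- 1 / fitdat$d_est_sem^2
  w[!is.finite(w)] <- 0
  if (all(w == 0)) w <- rep(1, nrow(fitdat))
  fit <- lm(d_est_mean ~ d_true + I(d_true^2), data = fitdat, weights = w)
  coeffs <- unname(coef(fit))
  structure(list(table = tab, coeffs = coeffs,
                 valid_range = range(fitdat$d_true),
                 loc_sigma = loc_sigma, overcount_mean = overcount_mean,
                 density_factor = density_factor,
                 neighbor_rank = neighbor_rank),
            class = "calibration_curve")
}

#' Predict the estimated diameter from a calibration curve
#'
#' @param curve a `calibration_curve`.
#' @param d_true true diameters (nm).
#' @return predicted estimated (apparent) diameters (nm).
#' @export
predict_d_est <- function(curve, d_true) {
  curve$coeffs[1] + curve$coeffs[2] * d_true + curve$coeffs[3] * d_true^2
}

#' Correct a measured island diameter for localization-precision bias
#'
#' Inverts the fitted quadratic `d_est(d_true)` on its monotone branch.
#' Intended for the mean of a measured diameter distribution (the curve
#' is built from per-field means); per-island use is possible but the
#' bias correction is calibrated for means.
#'
#' @param d_est measured (apparent) diameter(s), nm.
#' @param curve a `calibration_curve`.
#' @return estimated true diameter(s), nm.  Values below the curve's
#'   minimum output are clipped to the lower edge of the valid range
#'   with a warning.
#' @export
correct_diameter <- function(d_est, curve) {
  c0 <- curve$coeffs[1]; c1 <- curve$coeffs[2]; c2 <- curve$coeffs[3]
  d_floor <- 5   # no island below the 13-nm definition maps further down
  vapply(d_est, function(de) {
    if (abs(c2) < 1e-10) {
      out <- (de - c0) / c1
    } else {
      disc <- c1^2 - 4 * c2 * (c0 - de)
      if (disc < 0) return(NA_real_)
      roots <- sort((-c1 + c(-1, 1) * sqrt(disc)) / (2 * c2))
      vertex <- -c1 / (2 * c2)
      ## monotone-increasing branch of the parabola
      out <- if (c2 < 0) roots[roots <= vertex][1] else roots[roots >= vertex][1]
      if (is.na(out)) return(NA_real_)
    }
    if (out < d_floor) {
      warning("apparent diameter ", signif(de, 3),
              " nm below the calibrated output range; clipping")
      out <- d_floor
    }
    out
  }, numeric(1))
}

#' Apparent diameters of ground-truth islands in a segmented scene
#'
#' For each true island, the detected object with the most member
#' localizations whose centroid falls within `r_match` of the true
#' center (NA when none does) — the same convention the calibration
#' fields use for their central island.
#'
#' @param islands detected `island_records` (from
#'   [segment_fa_and_islands()] or [detect_objects()]).
#' @param truth data.frame with true island centers `x`, `y`.
#' @param r_match matching radius (nm), typically
#'   `d_true / 2 + 2 * sigma + 10`.
#' @return numeric vector of apparent diameters, one per true island.
#' @export
match_island_diameters <- function(islands, truth, r_match) {
  vapply(seq_len(nrow(truth)), function(i) {
    d2 <- (islands$cx - truth$x[i])^2 + (islands$cy - truth$y[i])^2
    hit <- which(d2 <= r_match^2)
    if (!length(hit)) return(NA_real_)
    islands$diameter[hit[which.max(islands$n_locs[hit])]]
  }, numeric(1))
}

#' Select the optimal Voronoi density factor
#'
#' Rebuilds the zero-localization-error calibration for each candidate
#' factor and scores it by the closeness metric
#' `sum over d = 30, 40, ..., 100 of (d_est(d) - d)^2 / d^2`; the factor
#' minimizing the metric is returned.
#'
#' @param candidate_factors numeric vector of density factors.
#' @param seed integer seed.
#' @param overcount_mean blinking overcount used in the simulated fields
#'   (1.4).
#' @param n_images replicate fields per diameter (30).
#' @return list: `factor` (the winner), `metrics` (data.frame factor,
#'   closeness), `curves`.
#' @export
select_density_factor <- function(candidate_factors = c(1.2, 1.45, 2.0),
                                  seed = NULL, overcount_mean = 1.4,
                                  n_images = 30) {
  if (!is.null(seed)) set.seed(seed)
  d_grid <- seq(30, 100, by = 10)
  curves <- lapply(candidate_factors, function(f)
    build_calibration(loc_sigma = 0, overcount_mean = overcount_mean,
                      d_true_grid = d_grid, n_images = n_images,
                      density_factor = f))
  metrics <- vapply(curves, function(cv) {
    tb <- cv$table
    sum((tb$d_est_mean - tb$d_true)^2 / tb$d_true^2)
  }, numeric(1))
  list(factor = candidate_factors[which.min(metrics)],
       metrics = data.frame(factor = candidate_factors,
                            closeness = metrics),
       curves = curves)
}

#' Detectability of islands of a given true diameter
#'
#' Fraction of simulated single-island fields in which the central
#' island is detected by the tessellation segmentation (density factor
#' 1.45, minimum diameter 13 nm, minimum 6 localizations).  Background
#' false positives are ignored: only the central ground-truth island
#' counts.
#'
#' @param d_true true island diameter (nm).
#' @param loc_sigma localization SD (nm).
#' @param island_density island spot density (0.02 or 0.04 per nm^2).
#' @param overcount_mean blinking overcount (1.4).
#' @param n_images number of simulated fields.
#' @param density_factor,min_locs detection settings.
#' @param seed integer seed.
#' @return detected fraction in [0, 1].
#' @export
detectability <- function(d_true, loc_sigma = 29, island_density = 0.02,
                          overcount_mean = 1.4, n_images = 30,
                          density_factor = 1.45, min_locs = 6,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fields <- simulate_calibration_field(
    d_true, loc_sigma, overcount_mean, n_images,
    island_spot_density = island_density)
  d_est <- vapply(fields, measure_central_island, numeric(1),
                  density_factor = density_factor, min_locs = min_locs)
  mean(!is.na(d_est))
}
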