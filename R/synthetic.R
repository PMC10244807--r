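#' Scene configuration for synthetic focal-adhesion fields
#'
#' Describes the ground-truth structure the generators emulate: circular
#' protein islands (disks) grouped into loose clusters of ~300 nm diameter
#' inside a focal-adhesion (FA) polygon, molecules placed uniformly inside
#' islands at `island_density` and outside at `background_density`.
#'
#' Densities here are *molecule* densities (molecules/nm^2); blinking
#' multiplies the resulting localization count by the mean number of
#' on-events per molecule (see [simulate_blinking()]).  In contrast, the
#' single-island calibration fields of [simulate_calibration_field()]
#' specify *spot* (on-event) densities, matching the convention of the
#' Monte-Carlo size-correction calibration.
#'
#' @param fa_polygon list with `x`, `y` vertex vectors (nm) of a closed
#'   polygon.  Default: a 3000 x 1500 nm rectangle.
#' @param island_diameter_law function(n) returning n true island
#'   diameters (nm), or a single number for fixed diameters.
#' @param island_density molecules/nm^2 inside islands (default
#'   0.02/1.4, so that with mEos3.2 blinking the localization density is
#'   0.02/nm^2, ten-fold over background).
#' @param background_density molecules/nm^2 outside islands.
#' @param cluster_diameter loose-cluster diameter (nm), default 300.
#' @param n_clusters number of loose clusters.
#' @param islands_per_cluster islands per loose cluster.
#' @param min_island_gap minimum center-to-center island spacing (nm);
#'   0 (default) permits overlap, emulating unresolved merged islands.
#'   Parameter-recovery scenes set this above the blur scale so every
#'   island is resolvable.
#' @param field_margin margin of sparse membrane around the FA polygon
#'   (nm); the full field is the polygon bounding box plus this margin.
#' @param outer_density molecule density outside the FA polygon
#'   (default one tenth of `background_density`, emulating the lower
#'   protein density of the bulk basal membrane).
#' @param seed integer seed (optional).
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(fa_polygon = NULL,
                         island_diameter_law = 32,
                         island_density = 0.02 / 1.4,
                         background_density = 0.002 / 1.4,
                         cluster_diameter = 300,
                         n_clusters = 3,
                         islands_per_cluster = 5,
                         min_island_gap = 0,
                         field_margin = 2000,
                         outer_density = NULL,
                         seed = NULL) {
  if (is.null(fa_polygon))
    fa_polygon <- list(x = c(0, 3000, 3000, 0), y = c(0, 0, 1500, 1500))
  if (is.numeric(island_diameter_law)) {
    d_fix <- island_diameter_law
    island_diameter_law <- function(n) rep(d_fix, n)
  }
  stopifnot(island_density > background_density, background_density > 0,
            cluster_diameter > 0, islands_per_cluster >= 0,
            field_margin >= 0)
  if (is.null(outer_density)) outer_density <- background_density / 10
  structure(list(fa_polygon = fa_polygon,
                 island_diameter_law = island_diameter_law,
                 island_density = island_density,
                 background_density = background_density,
                 cluster_diameter = cluster_diameter,
                 n_clusters = n_clusters,
                 islands_per_cluster = islands_per_cluster,
                 min_island_gap = min_island_gap,
                 field_margin = field_margin,
                 outer_density = outer_density,
                 seed = seed),
            class = "scene_config")
}

#' Fluorophore photophysics configuration
#'
#' @param p_bleach per-on-event bleaching probability in (0, 1]; the number
#'   of on-events per fluorescent molecule is Geometric with mean
#'   `1/p_bleach` (1.4 for mEos3.2, 2.7 for HMSiR).
#' @param on_time_tau stretched-exponential on-time constant (ms).
#' @param on_time_alpha stretching exponent in (0, 1].
#' @param mean_photons exponential mean photons per on-event.
#' @param fluorescent_fraction fraction of tags that are fluorescent.
#' @param loc_sigma localization error SD of one merged on-event (nm).
#' @param frame_time frame interval (ms).
#' @return list of class `photophysics_config`.
#' @export
photophysics_config <- function(p_bleach = 1 / 1.4, on_time_tau = 2,
                                on_time_alpha = 0.7, mean_photons = 49,
                                fluorescent_fraction = 0.60,
                                loc_sigma = 29, frame_time = 1) {
  stopifnot(p_bleach > 0, p_bleach <= 1,
            fluorescent_fraction > 0, fluorescent_fraction <= 1,
            loc_sigma >= 0, on_time_alpha > 0, on_time_alpha <= 1)
  structure(list(p_bleach = p_bleach, on_time_tau = on_time_tau,
                 on_time_alpha = on_time_alpha, mean_photons = mean_photons,
                 fluorescent_fraction = fluorescent_fraction,
                 loc_sigma = loc_sigma, frame_time = frame_time),
            class = "photophysics_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

point_in_poly <- function(x, y, poly) {
  pracma::inpolygon(x, y, poly$x, poly$y)
}

poly_area <- function(poly) abs(pracma::polyarea(poly$x, poly$y))

## uniform points inside a polygon by rejection from the bounding box
runif_in_polygon <- function(n, poly) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  bx <- range(poly$x); by <- range(poly$y)
  out_x <- numeric(0); out_y <- numeric(0)
  frac <- poly_area(poly) / ((bx[2] - bx[1]) * (by[2] - by[1]))
  while (length(out_x) < n) {
    m <- ceiling((n - length(out_x)) / max(frac, 0.05)) + 10
    x <- runif(m, bx[1], bx[2]); y <- runif(m, by[1], by[2])
    keep <- point_in_poly(x, y, poly)
    out_x <- c(out_x, x[keep]); out_y <- c(out_y, y[keep])
  }
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

#' Generate a ground-truth focal-adhesion scene
#'
#' Places loose clusters inside the FA polygon, circular islands inside
#' each cluster disk (islands must lie fully inside the polygon; overlap
#' between islands is permitted), then draws molecule positions uniformly
#' at `island_density` inside islands and `background_density` elsewhere
#' in the polygon.
#'
#' @param config a [scene_config()].
#' @return list with `molecules` (data.frame `x, y, island_id`;
#'   island_id 0 = FA background, -1 = sparse outer membrane),
#'   `islands` (data.frame `island_id, cluster_id, x, y, d_true`),
#'   `clusters`, `roi` (field rectangle, nm) and the config.
#' @export
generate_fa_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  poly <- config$fa_polygon
  rc <- config$cluster_diameter / 2

  ## cluster centers: uniform in polygon, kept a cluster radius off the edge
  ## where possible (rejection with fallback to unconstrained placement)
  centers <- runif_in_polygon(200 * config$n_clusters, poly)
  d_edge <- apply(centers, 1, function(p)
    min(sqrt((p[1] - poly$x)^2 + (p[2] - poly$y)^2)))
  ok <- which(d_edge > rc)
  idx <- if (length(ok) >= config$n_clusters) ok[seq_len(config$n_clusters)]
         else seq_len(config$n_clusters)
  centers <- centers[idx, , drop = FALSE]

  islands <- NULL
  if (config$islands_per_cluster > 0 && config$n_clusters > 0) {
    rows <- list()
    k <- 0L
    for (ci in seq_len(nrow(centers))) {
      need <- config$islands_per_cluster
      tries <- 0L
      while (need > 0 && tries < 2000L) {
        tries <- tries + 1L
        d <- config$island_diameter_law(1)
        if (d < 0) stop("island diameter law produced a negative diameter")
        ang <- runif(1, 0, 2 * pi); rad <- rc * sqrt(runif(1))
        cx <- centers[ci, 1] + rad * cos(ang)
        cy <- centers[ci, 2] + rad * sin(ang)
        ## island disk must lie inside the FA polygon and respect the
        ## minimum spacing if one is requested
        chk <- seq(0, 2 * pi, length.out = 8)
        ok_gap <- TRUE
        if (config$min_island_gap > 0 && k > 0) {
          prev <- do.call(rbind, rows)
          ok_gap <- all((prev$x - cx)^2 + (prev$y - cy)^2 >=
                          config$min_island_gap^2)
        }
        if (ok_gap && all(point_in_poly(cx + d / 2 * cos(chk),
                                        cy + d / 2 * sin(chk), poly))) {
          k <- k + 1L
          rows[[k]] <- data.frame(island_id = k, cluster_id = ci,
                                  x = cx, y = cy, d_true = d)
          need <- need - 1L
        }
      }
    }
    islands <- do.call(rbind, rows)
  }

  mol <- list()
  if (!is.null(islands)) {
    for (i in seq_len(nrow(islands))) {
      r <- islands$d_true[i] / 2
      n <- rpois(1, config$island_density * pi * r^2)
      if (n > 0) {
        ang <- runif(n, 0, 2 * pi); rad <- r * sqrt(runif(n))
        mol[[length(mol) + 1]] <-
          data.frame(x = islands$x[i] + rad * cos(ang),
                     y = islands$y[i] + rad * sin(ang),
                     island_id = islands$island_id[i])
      }
    }
  }
  ## background: CSR in polygon, thinned outside islands
  n_bg <- rpois(1, config$background_density * poly_area(poly))
  if (n_bg > 0) {
    bg <- runif_in_polygon(n_bg, poly)
    if (!is.null(islands)) {
      inside_any <- rep(FALSE, nrow(bg))
      for (i in seq_len(nrow(islands)))
        inside_any <- inside_any |
          ((bg[, 1] - islands$x[i])^2 + (bg[, 2] - islands$y[i])^2 <
             (islands$d_true[i] / 2)^2)
      bg <- bg[!inside_any, , drop = FALSE]
    }
    if (nrow(bg) > 0)
      mol[[length(mol) + 1]] <-
        data.frame(x = bg[, 1], y = bg[, 2], island_id = 0L)
  }
  ## sparse outer membrane around the FA polygon
  roi <- c(range(poly$x) + c(-1, 1) * config$field_margin,
           range(poly$y) + c(-1, 1) * config$field_margin)
  outer_area <- (roi[2] - roi[1]) * (roi[4] - roi[3]) - poly_area(poly)
  n_out <- rpois(1, config$outer_density * outer_area)
  got <- 0L
  while (got < n_out) {
    m <- 2 * (n_out - got) + 10
    x <- runif(m, roi[1], roi[2]); y <- runif(m, roi[3], roi[4])
    keep <- !point_in_poly(x, y, poly)
    x <- x[keep]; y <- y[keep]
    take <- min(length(x), n_out - got)
    if (take > 0)
      mol[[length(mol) + 1]] <- data.frame(x = x[seq_len(take)],
                                           y = y[seq_len(take)],
                                           island_id = -1L)
    got <- got + take
  }
  molecules <- if (length(mol)) do.call(rbind, mol)
               else data.frame(x = numeric(0), y = numeric(0),
                               island_id = integer(0))
  rownames(molecules) <- NULL
  list(molecules = molecules, islands = islands,
       clusters = data.frame(cluster_id = seq_len(nrow(centers)),
                             x = centers[, 1], y = centers[, 2],
                             diameter = config$cluster_diameter),
       roi = roi, config = config)
}

#' Simulate single-island calibration fields
#'
#' Reproduces the Monte-Carlo fields used to calibrate the tessellation
#' size estimate: one circular island of true diameter `d_true` centered
#' in a square of side `10 * d_true` (`20 * d_true` for `d_true <= 20` nm),
#' with fluorescent-spot number densities of 0.02/nm^2 inside and
#' 0.002/nm^2 outside.  Molecules are placed at `density / overcount_mean`
#' and each produces a Geometric(`1/overcount_mean`) number of on-events,
#' so the realized spot density matches the target on average; every spot
#' gets independent isotropic Gaussian position noise of SD `loc_sigma`.
#'
#' @param d_true true island diameter (nm), >= 13.
#' @param loc_sigma localization error SD (nm).
#' @param overcount_mean mean on-events per molecule (1.4 mEos3.2,
#'   2.7 HMSiR; 1 = no blinking).
#' @param n_images number of independent replicate fields.
#' @param seed integer seed (optional).
#' @param island_spot_density,background_spot_density target localization
#'   densities (spots/nm^2).
#' @return list of `n_images` [loc_table()]s; each carries attributes
#'   `side` (nm), `center`, `d_true`.
#' @export
simulate_calibration_field <- function(d_true, loc_sigma, overcount_mean,
                                       n_images = 30, seed = NULL,
                                       island_spot_density = 0.02,
                                       background_spot_density = 0.002) {
  stopifnot(d_true >= 13, loc_sigma >= 0, overcount_mean >= 1)
  if (n_images < 1) stop("n_images must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  side <- if (d_true <= 20) 20 * d_true else 10 * d_true
  ctr <- side / 2
  r <- d_true / 2
  p <- 1 / overcount_mean
  lam_in <- island_spot_density / overcount_mean * pi * r^2
  lam_out <- background_spot_density / overcount_mean * (side^2 - pi * r^2)

  one <- function() {
    n_in <- rpois(1, lam_in)
    ang <- runif(n_in, 0, 2 * pi); rad <- r * sqrt(runif(n_in))
    xs <- ctr + rad * cos(ang); ys <- ctr + rad * sin(ang)
    n_out <- rpois(1, lam_out)
    bx <- by <- numeric(0)
    while (length(bx) < n_out) {   # rejection: uniform in square minus disk
      m <- n_out - length(bx)
      x <- runif(2 * m + 10, 0, side); y <- runif(2 * m + 10, 0, side)
      keep <- (x - ctr)^2 + (y - ctr)^2 >= r^2
      bx <- c(bx, x[keep]); by <- c(by, y[keep])
    }
    mx <- c(xs, bx[seq_len(n_out)]); my <- c(ys, by[seq_len(n_out)])
    n_mol <- length(mx)
    nev <- rgeom(n_mol, p) + 1L
    id <- rep.int(seq_len(n_mol), nev)
    x <- mx[id] + rnorm(length(id), 0, loc_sigma)
    y <- my[id] + rnorm(length(id), 0, loc_sigma)
    lt <- loc_table(frame = seq_along(id), x_nm = x, y_nm = y,
                    photons = NA_real_, uncertainty_nm = loc_sigma,
                    molecule_id = id,
                    in_island = rep.int(seq_len(n_mol) <= n_in, nev))
    attr(lt, "side") <- side
    attr(lt, "center") <- c(ctr, ctr)
    attr(lt, "d_true") <- d_true
    lt
  }
  lapply(seq_len(n_images), function(i) one())
}

## stretched-exponential on-time sampler: density p(t) proportional to
## exp(-(t/tau)^alpha), the shape the on-period histograms follow.
## With G ~ Gamma(shape = 1/alpha), t = tau * G^(1/alpha) has exactly
## this density (alpha = 1 reduces to the exponential).
rstretched_exp <- function(n, tau, alpha) {
  tau * rgamma(n, shape = 1 / alpha)^(1 / alpha)
}

#' Simulate blinking localizations from ground-truth molecules
#'
#' A fraction `fluorescent_fraction` of molecules emit.  Each fluorescent
#' molecule produces a Geometric(`p_bleach`) number of on-events at
#' uniformly random start frames; each on-event lasts a stretched-
#' exponential on-time discretized to `ceiling(on_time / frame_time)`
#' frames (truncated at the acquisition end), with the exponential total
#' photon count split evenly over its frames.  Every per-frame
#' localization is the true position plus isotropic Gaussian noise of
#' SD `loc_sigma * sqrt(event frames)` — `loc_sigma` is the precision
#' of the whole on-event, recovered when the frames are merged.
#'
#' @param molecules data.frame with `x`, `y` (nm) and optionally
#'   `island_id`.
#' @param phot a [photophysics_config()].
#' @param n_frames acquisition length in frames.
#' @param seed integer seed (optional).
#' @return a [loc_table()] with `molecule_id` and `event_id` columns.
#' @export
simulate_blinking <- function(molecules, phot, n_frames, seed = NULL) {
  stopifnot(inherits(phot, "photophysics_config"), n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_mol <- nrow(molecules)
  fluor <- which(rbinom(n_mol, 1, phot$fluorescent_fraction) == 1)
  if (length(fluor) == 0)
    return(loc_table(frame = integer(0), x_nm = numeric(0),
                     y_nm = numeric(0), molecule_id = integer(0),
                     event_id = integer(0)))
  nev <- rgeom(length(fluor), phot$p_bleach) + 1L
  mol_of_event <- rep.int(fluor, nev)
  n_events <- length(mol_of_event)
  start <- sample.int(n_frames, n_events, replace = TRUE)
  on_t <- rstretched_exp(n_events, phot$on_time_tau, phot$on_time_alpha)
  len <- pmax(1L, ceiling(on_t / phot$frame_time))
  len <- pmin(len, n_frames - start + 1L)
  tot_phot <- rexp(n_events, 1 / phot$mean_photons)

  ev <- rep.int(seq_len(n_events), len)
  off <- sequence(len) - 1L
  frame <- start[ev] + off
  mid <- mol_of_event[ev]
  ## loc_sigma is the per-ON-EVENT precision (from the photons of the
  ## whole on-period); a frame carries only 1/len of those photons, so
  ## its error SD is loc_sigma * sqrt(len), and the photon-weighted
  ## merge of the event's frames recovers SD loc_sigma
  sd_frame <- phot$loc_sigma * sqrt(len[ev])
  x <- molecules$x[mid] + rnorm(length(ev), 0, sd_frame)
  y <- molecules$y[mid] + rnorm(length(ev), 0, sd_frame)
  out <- loc_table(frame = frame, x_nm = x, y_nm = y,
                   photons = tot_phot[ev] / len[ev],
                   uncertainty_nm = sd_frame,
                   molecule_id = mid, event_id = ev)
  if (!is.null(molecules$island_id)) out$island_id <- molecules$island_id[mid]
  out <- out[order(out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("loc_table", "data.frame")
  out
}

#' Hop-diffusion simulation configuration
#'
#' Compartmentalized ("picket-fence") 2-D diffusion: a random walk on a
#' square compartment lattice of edge `L_true`; a substep that would cross
#' a compartment boundary succeeds with probability `hop_probability`,
#' otherwise the walker is reflected at the boundary.
#'
#' @param L_true compartment edge length (nm).
#' @param D_micro microscopic diffusion coefficient (um^2/s).
#' @param hop_probability barrier-crossing probability per encounter.
#' @param frame_time frame interval (ms).
#' @param n_steps number of recorded frames.
#' @param substeps_per_frame simulation substeps per frame (>= 10 so a
#'   single substep displacement is much smaller than `L_true`).
#' @param loc_sigma localization noise SD added to recorded positions (nm).
#' @param seed integer seed (optional).
#' @export
hop_sim_config <- function(L_true = 109, D_micro = 5, hop_probability = 1,
                           frame_time = 1 / 6, n_steps = 1500,
                           substeps_per_frame = 50, loc_sigma = 0,
                           seed = NULL) {
  stopifnot(L_true > 0, D_micro > 0, hop_probability >= 0,
            hop_probability <= 1, substeps_per_frame >= 10, n_steps >= 2)
  structure(list(L_true = L_true, D_micro = D_micro,
                 hop_probability = hop_probability, frame_time = frame_time,
                 n_steps = n_steps, substeps_per_frame = substeps_per_frame,
                 loc_sigma = loc_sigma, seed = seed),
            class = "hop_sim_config")
}

#' Simulate one hop-diffusion trajectory
#'
#' @param config a [hop_sim_config()].
#' @return data.frame `frame, x_nm, y_nm` (noisy recorded positions) with
#'   attributes `true_x`, `true_y` (noise-free frame positions),
#'   `dwell_ms` (completed ground-truth compartment residency times, ms)
#'   and `config`.
#' @export
simulate_hop_trajectory <- function(config) {
  stopifnot(inherits(config, "hop_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  D_nm2_ms <- config$D_micro * 1000          # 1 um^2/s = 1000 nm^2/ms
  dt_sub <- config$frame_time / config$substeps_per_frame
  sigma_step <- sqrt(2 * D_nm2_ms * dt_sub)
  ## start at a uniform position within the central compartment
  x0 <- runif(1, 0, config$L_true); y0 <- runif(1, 0, config$L_true)
  sim <- hop_sim_cpp(config$n_steps, config$substeps_per_frame,
                     config$L_true, sigma_step, config$hop_probability,
                     x0, y0)
  x <- sim$x; y <- sim$y
  xn <- x + rnorm(length(x), 0, config$loc_sigma)
  yn <- y + rnorm(length(y), 0, config$loc_sigma)
  out <- data.frame(frame = seq_along(x), x_nm = xn, y_nm = yn)
  attr(out, "true_x") <- x
  attr(out, "true_y") <- y
  attr(out, "dwell_ms") <- sim$dwell_substeps * dt_sub
  attr(out, "censored_ms") <- sim$censored_substeps * dt_sub
  attr(out, "config") <- config
  out
}

#' Hop probability giving a target compartment residency time
#'
#' First-order kinetics: the boundary-encounter rate per axis is
#' `E|dx| / L` per substep, so the escape rate is proportional to the hop
#' probability.  The analytic guess is refined by one short calibration
#' simulation (deterministic under `seed`).
#'
#' @param L_true,D_micro,frame_time,substeps_per_frame as in
#'   [hop_sim_config()].
#' @param tau_target desired mean residency time (ms).
#' @param seed seed for the calibration run.
#' @param calib_steps frames per calibration trajectory; long
#'   trajectories, because completed-dwell censoring biases the mean
#'   dwell low on short ones (the dwell distribution is heavy-tailed).
#' @return hop probability in (0, 1].
#' @export
hop_probability_for_tau <- function(L_true, D_micro, tau_target,
                                    frame_time = 1 / 6,
                                    substeps_per_frame = 50,
                                    seed = 1, calib_steps = 12000) {
  D_nm2_ms <- D_micro * 1000
  dt_sub <- frame_time / substeps_per_frame
  e_abs <- sqrt(2 * D_nm2_ms * dt_sub) * sqrt(2 / pi)
  p0 <- min(1, L_true * dt_sub / (2 * e_abs * tau_target))
  ## iterative refinement: measured mean dwell scales ~ 1/p
  measure_tau <- function(p, off) {
    cfg <- hop_sim_config(L_true, D_micro, p, frame_time, calib_steps,
                          substeps_per_frame, loc_sigma = 0)
    mean(unlist(lapply(seq_len(15), function(i) {
      cfg$seed <- seed + off + i
      attr(simulate_hop_trajectory(cfg), "dwell_ms")
    })))
  }
  p <- p0
  for (it in 1:3) {
    tau_meas <- measure_tau(p, 100 * it)
    if (!is.finite(tau_meas) || tau_meas <= 0) break
    if (abs(tau_meas / tau_target - 1) < 0.02) break
    p <- min(1, p * tau_meas / tau_target)
  }
  p
}

#' Ground-truth sidecar writer
#'
#' Serializes generator ground truth (island catalogue, molecule counts,
#' configs) next to a localization CSV as JSON.
#'
#' @param truth list of ground-truth components.
#' @param path output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  truth$config <- NULL   # closures are not serializable
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
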