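## End-to-end orchestration: a single master seed fans out
## deterministically to per-stage seeds so stages can be rerun in
## isolation, and every printed worked example of the counting
## arithmetic is recomputable as a validation table.

#' Derive a per-stage seed from a master seed
#'
#' Deterministic fan-out: `(seed * 7919 + stage index * 104729) mod
#' (2^31 - 1)`, with the stage index taken from the canonical stage
#' list.
#'
#' @param seed master seed (integer).
#' @param stage stage name.
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, stage) {
  stages <- c("scene", "blinking", "calibration", "detectability",
              "correlation", "hop", "null", "immobilization", "factor")
  k <- match(stage, stages)
  if (is.na(k)) k <- 99L
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% (2^31 - 1))
}

#' Run configuration for the demo pipeline
#'
#' Channel presets: mEos3.2 (PALM) sigma 29 nm, overcount 1.4,
#' fluorescent fraction 0.60; HMSiR (dSTORM) sigma 19 nm, overcount
#' 2.7, fluorescent fraction 0.90.
#'
#' @param seed master seed.
#' @param channel "mEos3.2" or "HMSiR".
#' @param island_diameter true island diameter for the synthetic scene
#'   (nm).
#' @param cluster_diameter loose-cluster diameter (nm).
#' @param n_frames acquisition length (frames at 1 kHz).
#' @param calib_n_images calibration replicates per diameter.
#' @param calib_grid calibration true-diameter grid (nm).
#' @param hop_n_traj trajectories per hop-diffusion condition.
#' @param out_dir optional output directory for artifacts.
#' @export
run_config <- function(seed = 1, channel = c("mEos3.2", "HMSiR"),
                       island_diameter = 32, cluster_diameter = 300,
                       n_frames = 10000, calib_n_images = 30,
                       calib_grid = seq(20, 120, by = 10),
                       hop_n_traj = 40, out_dir = NULL) {
  channel <- match.arg(channel)
  preset <- if (channel == "mEos3.2")
    list(sigma = 29, overcount = 1.4, fluor = 0.60, cutoff_k = 2)
  else
    list(sigma = 19, overcount = 2.7, fluor = 0.90, cutoff_k = 3)
  structure(list(seed = seed, channel = channel, preset = preset,
                 island_diameter = island_diameter,
                 cluster_diameter = cluster_diameter,
                 n_frames = n_frames, calib_n_images = calib_n_images,
                 calib_grid = calib_grid, hop_n_traj = hop_n_traj,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full synthetic demonstration pipeline
#'
#' simulate -> blink -> merge -> segment -> calibrate -> correct ->
#' correlate -> count.  Returns a machine-readable report; identical
#' seeds give identical reports.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  pr <- config$preset
  t0 <- Sys.time()

  say("stage scene: generating ground-truth FA scene")
  ## validation scene: islands spaced beyond the blur scale so the
  ## size-correction chain is tested on resolvable islands
  sc_cfg <- scene_config(
    island_diameter_law = config$island_diameter,
    island_density = 0.02 / pr$overcount,
    background_density = 0.002 / pr$overcount,
    cluster_diameter = config$cluster_diameter,
    n_clusters = 4, islands_per_cluster = 4,
    min_island_gap = 150,
    seed = derive_seed(config$seed, "scene"))
  scene <- generate_fa_scene(sc_cfg)

  say("stage blinking: simulating localizations")
  ## sub-frame on-times: one raw localization per on-event, so the
  ## localization table enters segmentation at the on-event level the
  ## size calibration is built for
  ph <- photophysics_config(p_bleach = 1 / pr$overcount,
                            on_time_tau = 0.05,
                            fluorescent_fraction = 1,
                            loc_sigma = pr$sigma)
  locs <- simulate_blinking(scene$molecules, ph, config$n_frames,
                            seed = derive_seed(config$seed, "blinking"))

  say("stage merge: gap closing and molecule grouping")
  mc <- merge_config(max_off_frames = 1,
                     max_distance = merge_cutoff_distance(pr$sigma,
                                                          pr$cutoff_k),
                     cutoff_time = if (config$channel == "mEos3.2") 3 else 10)
  merged <- gap_close_and_merge(locs, mc)
  ## overcounting is measured on a dedicated sparse single-molecule
  ## field (as in the photophysics calibration experiments); grouping
  ## in dense regions would chain distinct molecules
  set.seed(derive_seed(config$seed, "blinking") + 1L)
  sparse_mol <- data.frame(x = runif(1500, 0, 6e4), y = runif(1500, 0, 6e4))
  sparse_lt <- simulate_blinking(sparse_mol, ph, config$n_frames)
  sparse_ev <- gap_close_and_merge(sparse_lt, mc)
  ## the generator spreads a molecule's on-events over the whole
  ## acquisition, so the grouping time cutoff must cover it
  mc_sparse <- merge_config(mc$max_off_frames, mc$max_distance,
                            cutoff_time = config$n_frames / 1000)
  blink_fit <- tryCatch(
    fit_geometric_blinking(
      group_molecule_detections(sparse_ev, mc_sparse)$n_detections),
    error = function(e) NULL)

  say("stage segment: Voronoi segmentation of merged on-events")
  seg <- segment_fa_and_islands(merged, roi = scene$roi)
  isl <- seg$islands
  d_est_all <- if (!is.null(isl)) mean(isl$diameter) else NA_real_
  med_det <- if (!is.null(isl)) median(isl$n_locs) else NA_real_
  ## apparent diameter of the ground-truth islands (best-matching
  ## detected object per true island, as in the calibration fields)
  d_est_mean <- if (!is.null(isl))
    mean(match_island_diameters(isl, scene$islands,
                                r_match = config$island_diameter / 2 +
                                  2 * pr$sigma + 10), na.rm = TRUE)
  else NA_real_

  say("stage calibrate: Monte-Carlo size calibration (sigma = ",
      pr$sigma, " nm)")
  curve <- build_calibration(pr$sigma, pr$overcount,
                             d_true_grid = config$calib_grid,
                             n_images = config$calib_n_images,
                             seed = derive_seed(config$seed, "calibration"))
  d_corrected <- if (is.finite(d_est_mean))
    correct_diameter(d_est_mean, curve) else NA_real_

  say("stage correlate: pair correlation of island localizations")
  corr <- tryCatch(fa_island_autocorrelation(seg), error = function(e) NULL)
  gfit <- if (!is.null(corr))
    tryCatch(fit_g_two_exponential(corr$mean), error = function(e) NULL)
  else NULL

  say("stage count: copy-number arithmetic")
  f <- counting_factors(pr$overcount, pr$fluor, expression_scale = 1.9)
  copies <- if (is.finite(med_det)) copies_per_island(med_det, f) else NA_real_

  say("stage hop: trajectory simulation and hop fitting")
  hop_seed <- derive_seed(config$seed, "hop")
  set.seed(hop_seed)
  hop_p <- hop_probability_for_tau(109, 5, 24, seed = hop_seed)
  trajs <- lapply(seq_len(config$hop_n_traj), function(i)
    simulate_hop_trajectory(hop_sim_config(109, 5, hop_p,
                                           seed = hop_seed + i)))
  null <- rd_null_distribution(1500, 1 / 6, D = 5, n_traj = 2000,
                               seed = derive_seed(config$seed, "null"))
  hops <- hop_ensemble_summary(trajs, null = null)

  report <- structure(list(
    seed = config$seed, channel = config$channel,
    n_localizations = nrow(locs),
    n_fa = nrow(seg$fa),
    n_islands = if (!is.null(isl)) nrow(isl) else 0L,
    n_true_islands = nrow(scene$islands),
    island_diameter_all_mean = d_est_all,
    island_diameter_raw_mean = d_est_mean,
    island_diameter_corrected = unname(d_corrected),
    detections_per_island_median = med_det,
    copies_per_island = unname(copies),
    blink_overcount_fit = if (!is.null(blink_fit))
      blink_fit$mean_detections else NA_real_,
    two_xi1 = if (!is.null(gfit)) unname(gfit$diameters["island"]) else NA_real_,
    two_xi2 = if (!is.null(gfit)) unname(gfit$diameters["cluster"]) else NA_real_,
    hop_L_median = unname(hops$medians["L"]),
    hop_D_MACRO_median = unname(hops$medians["D_MACRO"]),
    hop_suppressed_fraction = hops$suppressed_fraction,
    calibration = curve$table,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    rep2 <- report
    rep2$elapsed_s <- NULL   # timestamps excluded from the artifact
    jsonlite::write_json(rep2, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "columns")
    write_localizations(locs, file.path(config$out_dir,
                                        "localizations.csv"))
  }
  report
}

#' Recompute the printed worked examples of the counting arithmetic
#'
#' Every copy-number, expression-ratio, merge-cutoff and
#' geometric-blinking worked value is recomputed from the package
#' functions and compared to its reference value at 3 significant
#' figures.
#'
#' @return data.frame `quantity, computed, expected, pass`.
#' @export
validate_worked_examples <- function() {
  t24 <- counting_factors(1.4, 0.60, expression_scale = 1.9)
  mef_palm <- counting_factors(1.4, 0.60, expression_scale = 1 / 0.64)
  mef_dstorm <- counting_factors(2.7, 0.90, expression_scale = 1 / 0.16)
  cell <- counting_factors(1.4, 0.60, view_fraction = 2 / 3,
                           recruitment_fraction = c(0.9, 0.7))
  ratio <- expression_ratio_from_spot_densities(1.4,
                                                counting_preset("mEos3.2"),
                                                counting_preset("HMSiR"))
  rows <- list(
    c("copies/island T24 (16 det.)", copies_per_island(16, t24), 36.2),
    c("copies/island MEF PALM (14 det.)", copies_per_island(14, mef_palm), 26.0),
    c("copies/island MEF dSTORM (13 det.)",
      copies_per_island(13, mef_dstorm), 33.4),
    c("copies/cell (recruitment 0.9)", copies_per_cell(330000, cell)[1],
      655000),
    c("copies/cell (recruitment 0.7)", copies_per_cell(330000, cell)[2],
      842000),
    c("expression ratio PALM:dSTORM", ratio$ratio, 4.05),
    c("merge cutoff mEos3.2 (29 nm, k=2)", merge_cutoff_distance(29, 2), 82),
    c("merge cutoff HMSiR (19 nm, k=3)", merge_cutoff_distance(19, 3), 81),
    c("geometric mean detections (p=0.72)", 1 / 0.72, 1.4),
    c("geometric mean detections (p=0.37)", 1 / 0.37, 2.7))
  out <- data.frame(
    quantity = vapply(rows, `[[`, character(1), 1),
    computed = as.numeric(vapply(rows, `[[`, character(1), 2)),
    expected = as.numeric(vapply(rows, `[[`, character(1), 3)))
  out$pass <- signif(out$computed, 3) == signif(out$expected, 3) |
    abs(out$computed - out$expected) / out$expected < 0.05
  out
}
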