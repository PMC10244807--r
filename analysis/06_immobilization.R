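#!/usr/bin/env Rscript
# Immobilization mapping: detect immobilization events in simulated
# receptor trajectories with island-biased stopping, map them onto a
# median-normalized (thermographic) density image of the adhesion, and
# measure the fraction of events in above-median territory.

library(nanofa)
dir.create("results", showWarnings = FALSE)
set.seed(5)

## adhesion scene rendered to a density image
scn <- generate_fa_scene(scene_config(seed = 5, min_island_gap = 150,
                                      islands_per_cluster = 4,
                                      cluster_diameter = 400, n_clusters = 4))
locs <- simulate_blinking(scn$molecules,
                          photophysics_config(on_time_tau = 0.05,
                                              fluorescent_fraction = 1,
                                              loc_sigma = 29),
                          10000, seed = 6)
img <- render(locs, pixel = 20, sigma = 29,
              xlim = scn$roi[1:2], ylim = scn$roi[3:4])
fa_mask <- binarize_image(img, "min_cross_entropy")
norm_map <- thermographic_normalize(img, fa_mask)
attr(norm_map, "pixel") <- 20
attr(norm_map, "xlim") <- scn$roi[1:2]
attr(norm_map, "ylim") <- scn$roi[3:4]
write_image_tiff(pmin(pmax(norm_map, 0), 6) / 6,
                 "results/thermographic_map.tiff")

## trajectories: with probability p_island a molecule immobilizes on a
## randomly chosen island; otherwise it keeps diffusing
p_island <- 0.7
sigma_sm <- 21; frame_time <- 4       # single-molecule channel, 250 Hz
events <- list()
for (k in 1:60) {
  on_island <- runif(1) < p_island
  if (on_island) {
    i <- sample(nrow(scn$islands), 1)
    cx <- scn$islands$x[i]; cy <- scn$islands$y[i]
  } else {
    cx <- runif(1, 0, 3000); cy <- runif(1, 0, 1500)
  }
  tr <- data.frame(frame = 1:48, x_nm = rnorm(48, cx, sigma_sm),
                   y_nm = rnorm(48, cy, sigma_sm))
  ev <- detect_immobilization(tr, sigma_sm, 15, frame_time = frame_time)
  if (nrow(ev)) events[[length(events) + 1]] <- ev[1, ]
}
events <- do.call(rbind, events)
write.csv(events, "results/immobilization_events.csv", row.names = FALSE)

out <- intensity_at_sites(norm_map, events)
message(nrow(events), " immobilization events; fraction in above-median ",
        "paxillin territory: ", round(out$fraction_above_1, 2),
        " (island-biased stopping probability was ", p_island, ")")
write.csv(data.frame(value = out$values),
          "results/immobilization_intensities.csv", row.names = FALSE)
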