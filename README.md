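# nanofa

Quantification of focal-adhesion (FA) nano-architecture from
single-molecule localization microscopy (SMLM) data.

Ultrafast live-cell PALM/dSTORM resolves FAs into an archipelago of
protein "islands" — nanoclusters of 13–100 nm diameter sitting in a
compartmentalized fluid membrane. Extracting that picture from a
localization table takes a chain of quantitative steps, each with its own
statistical pitfalls: fluorophores blink (one molecule yields a geometric
number `N ~ p(1-p)^(N-1)` of on-events, so raw counts overcount
molecules), localization error inflates apparent cluster sizes, and
single-molecule trajectories must be classified against a proper Brownian
null before "confined diffusion" can be claimed. `nanofa` implements that
chain for R, together with synthetic-data generators that emulate the
statistical structure each stage assumes, so every stage can be validated
by parameter recovery without any experimental download.

The package is aimed at microscopists and image analysts working with
localization tables (CSV: `frame, x_nm, y_nm, photons, uncertainty_nm`)
and single-particle trajectories (`frame, x_nm, y_nm`).

## What is implemented

* **Photophysics** — stretched-exponential on-time fits
  `phi(t) = phi0 exp(-(t/tau)^alpha)`, exponential photon-count fits,
  geometric blinking fits (overcounting factor `1/p`), Mortensen-type
  localization precision with camera excess noise, spot-survival curves.
* **Localization processing** — 1-frame gap closing and merging
  (cutoff `k*sqrt(2)*sigma`: 82 nm PALM, 81 nm dSTORM), molecule
  grouping, Gaussian rendering, sliding-window reconstruction,
  recruitment time-courses.
* **Voronoi segmentation** — SR-Tesseler-style density thresholding
  (factor 1.45) in two passes: FAs (min area = 178-nm circle), then
  islands inside each FA (>= 13 nm, >= 6 localizations,
  `d = 2*sqrt(A/pi)`); plus minimum-cross-entropy and Sauvola
  binarization.
* **Monte-Carlo size correction** — calibration of apparent vs true
  island diameter under 19/29-nm localization error and geometric
  blinking; quadratic inversion; density-factor selection by the
  closeness metric; island detectability by size.
* **Pair correlation** — FFT auto-/cross-correlation with exact mask
  edge correction; two-exponential `g(r)` fits (island scale `2*xi1`,
  loose-cluster scale `2*xi2`); exponential `c(r)` tail fits.
* **Molecular counting** — detections -> copies via overcounting,
  fluorescent fraction and expression scale, with channel presets
  (mEos3.2: 1.4, 0.60; HMSiR: 2.7, 0.90).
* **Hop diffusion** — picket-fence trajectory simulator (compartment
  edge `L`, barrier-crossing probability), time-averaged MSD, hop-model
  fits for `L` and `D_MACRO`, RD motional-mode classification against a
  5,000-trajectory Brownian null, truncated-exponential residency
  lifetimes, Brunner-Munzel comparisons.
* **Immobilization mapping** — gyration-radius event detection,
  thermographic (median) normalization of density images, enrichment of
  immobilization sites.

## A worked example

```r
library(nanofa)

## a synthetic FA: 32-nm islands in loose clusters, mEos3.2 photophysics
scn  <- generate_fa_scene(scene_config(seed = 5, min_island_gap = 150,
                                       islands_per_cluster = 4,
                                       cluster_diameter = 400,
                                       n_clusters = 4))
locs <- simulate_blinking(scn$molecules,
                          photophysics_config(on_time_tau = 0.05,
                                              fluorescent_fraction = 1,
                                              loc_sigma = 29),
                          n_frames = 10000, seed = 55)
seg  <- segment_fa_and_islands(locs, roi = scn$roi)
dm   <- match_island_diameters(seg$islands, scn$islands, r_match = 84)
mean(dm, na.rm = TRUE)
#> [1] 56.8

## correct the apparent mean with the 29-nm Monte-Carlo calibration
cv <- build_calibration(29, 1.4, n_images = 30, seed = 1)
correct_diameter(mean(dm, na.rm = TRUE), cv)
#> [1] 28.9
```

The apparent mean diameter (~57 nm here) is what tessellation reports for
32-nm islands blurred by 29-nm localization error; inverting the
calibration recovers the true scale to within a few nm. The same
arithmetic applied to published FA data takes an apparent 59 nm to a true
~33 nm. Copy numbers follow the counting chain:

```r
validate_worked_examples()[, c("quantity", "computed", "expected")]
#>  copies/island T24 (16 det.)            36.19  36.2
#>  copies/island MEF PALM (14 det.)       26.04  26.0
#>  ...
```

The numbered scripts under `analysis/` run the full study as a sequence:
photophysics fits, calibration and detectability, scene segmentation and
counting, correlation analysis, hop diffusion, immobilization mapping;
each writes its tables under `results/`.

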