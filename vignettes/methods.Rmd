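---
title: "Quantifying focal-adhesion nano-architecture from SMLM localizations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying focal-adhesion nano-architecture from SMLM localizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nanofa` implements the quantification chain used in ultrafast live-cell
single-molecule localization microscopy (SMLM) studies of focal adhesions
(FAs): fluorophore photophysics, localization post-processing,
Voronoi-tessellation segmentation of FAs and FA-protein islands,
Monte-Carlo correction of island sizes for localization error, pair
correlation of island localizations, molecular counting, hop-diffusion
trajectory analysis, and immobilization-site mapping. Because raw data of
this kind are rarely deposited, the package ships first-class synthetic
generators that emulate the statistical structure every stage assumes, so
each stage has a parameter-recovery test surface.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices made where the published procedures leave
the details open, and what passing tests on synthetic data do and do not
establish about real data.

# Fluorophore photophysics

Three empirical laws describe the probes (mEos3.2 for PALM, HMSiR for
dSTORM):

* **On-period durations** follow a stretched exponential: the histogram of
  on-times is fitted with $\varphi(t) = \varphi_0\,
  e^{-(t/\tau)^\alpha}$, $0 < \alpha \le 1$. The generator samples
  on-times from the density proportional to $e^{-(t/\tau)^\alpha}$
  (equivalently $\tau G^{1/\alpha}$ with $G \sim \Gamma(1/\alpha)$), which
  is the distribution whose histogram has exactly the fitted shape;
  $\alpha = 1$ reduces to the exponential. Fits are weighted least squares
  with Poisson weights, 1-frame bins, zero bin excluded; quoted errors are
  68.3%-confidence fitting SEs.
* **Photons per on-period** are exponential; the decay constant of the
  histogram fit *is* the mean photon count (49 for mEos3.2 at its optimal
  excitation; 477 for HMSiR).
* **Detections per molecule** follow the geometric law
  $f(N) = p\,(1-p)^{N-1}$ of a monomeric blinking fluorophore. `p` is
  estimated by maximum likelihood, $\hat p = 1/\bar N$, which also matches
  the printed overcounting arithmetic ($1/p$ = 1.4 at $p = 0.72$; 2.7 at
  $p = 0.37$); the histogram curve-fit of the original analysis is kept as
  a chi-square goodness-of-fit overlay rather than as the estimator,
  because the ML estimate is unbiased and is the quantity the counting
  chain consumes.

Localization precision is converted from photon counts with the
maximum-likelihood estimator formula for EM-gain cameras,
$\sigma^2 = F\,\frac{\sigma_a^2}{N}\left(\frac{16}{9} +
\frac{8\pi \sigma_a^2 b^2}{N a^2}\right)$, $\sigma_a^2 =
s_{\mathrm{PSF}}^2 + a^2/12$, with excess-noise factor $F = 1.2$, pixel
size $a = 55.1$ nm and PSF SD 129 nm. The background variance $b^2$
behind the published 29-nm and 19-nm precisions is not printed anywhere,
so it is an explicit input; the tests verify only that a physically
modest $b^2$ reproduces 29 nm at 49 photons.

# Localization post-processing

Raw localization tables (one row per emitter per frame) are merged into
**on-events** by greedy nearest-neighbour linking in frame order with
1-frame gap closing and a spatial cutoff of $k\sqrt2\,\sigma$ rounded to
the nearest nm — the only reading of the published cutoffs consistent
with both printed values ($2\sqrt2 \times 29 = 82$ nm for PALM,
$3\sqrt2 \times 19 = 81$ nm for dSTORM). Merged positions are
photon-weighted means. Because linking operates on event end-frames,
merging is idempotent. On-events are further grouped into **molecules**
with the same spatial cutoff and a time cutoff (3 s for mEos3.2, 10 s for
HMSiR); the per-molecule detection counts feed the geometric blinking
fit. Grouping is reliable only in sparse fields — at FA-interior
densities distinct molecules chain together, which is why the molecular
counting chain uses the *fitted* overcounting factor from sparse
single-molecule data, never per-molecule grouping of dense data.

In `simulate_blinking`, `loc_sigma` is the precision of a merged
on-event; each individual frame gets noise `loc_sigma * sqrt(frames of
the event)` so that merging recovers `loc_sigma`. This mirrors how the
published precisions are defined (from the photons of the whole
on-period).

Rendering uses pixel-integrated unit-mass Gaussians (total intensity =
localization count up to edge loss): 10-nm pixels with a 29/19-nm
Gaussian for super-resolved images, 55.1-nm pixels with a 129-nm Gaussian
for diffraction-limited images. Sliding-window reconstruction and
per-circle recruitment time-courses follow directly.

# Voronoi segmentation

Per-localization densities come from the Dirichlet tessellation clipped
to a rectangular ROI (`deldir`). The default density is the first-rank
averaged density $\delta_i = (1 + |N(i)|) / (A_i + \sum_{j \in N(i)}
A_j)$, with polygons adjacent when they share a Voronoi edge. Objects are
connected components of polygons with $\delta_i \ge$ threshold; an
object's diameter is $d = 2\sqrt{A/\pi}$; islands require $d \ge 13$ nm
and $\ge 6$ localizations, FAs a minimum area equal to a 178-nm circle.

The published procedure does not restate the segmentation software's
internal density normalization, so three conventions had to be fixed.
They were fixed once, against the procedure's own published validation
anchors (the zero-error calibration tracking the identity line at factor
1.45, the factor-selection table, and the detectability fractions), and
then frozen:

* **FA pass** thresholds at `1.45 x (N / ROI area)` — the dataset-average
  density. FAs are several-fold enriched over the whole field, so this is
  insensitive to the exact convention.
* **Island pass** thresholds at `1.45 x mean per-localization density` of
  the parent FA's members. The localization-weighted mean is higher than
  the area mean in clustered data (repeated localizations of one molecule
  produce small, dense polygons); under this convention — and only under
  this one, among those tried — the zero-error calibration reproduces
  `d_est = d_true` at factor 1.45.
* **Object area** sums the member polygons that are dense in their own
  right ($1/A_i \ge$ threshold), while membership, counts and
  connectivity use the smoothed density. Edge polygons straddle the
  object boundary and extend far into the sparse surroundings; counting
  their full area would overstate the island footprint by roughly the
  inter-localization spacing of the background.

Raising the density factor can only shrink objects (monotonicity), and
islands are nested inside their parent FA by construction; both are
enforced by tests. Coincident localizations (possible at zero simulated
error) are deterministically jittered by 0.01 nm — far below any
physical length scale in the problem — because a tessellation requires
distinct sites.

Image binarization offers minimum-cross-entropy (Li) global thresholding
(used for FA contours in diffraction-limited images) and Sauvola local
thresholding (radius 64 px, k = 0.5, r = 128, used for cell outlines).

# Monte-Carlo size correction

Finite localization precision inflates the apparent diameter of a small
island. The calibration places one circular island of true diameter
$d_{\mathrm{true}}$ (20–120 nm in 10-nm steps) at the center of a square
of side $10\,d_{\mathrm{true}}$ ($20\,d_{\mathrm{true}}$ at 20 nm), with
fluorescent-spot densities 0.02/nm² inside and 0.002/nm² outside.
Molecules are placed at `density / overcount` and blink geometrically, so
the *realized spot density* matches the target — 0.02/nm² is a spot
(on-event) density, not a molecule density. Each spot gets Gaussian noise
of SD 0, 19 or 29 nm. Thirty fields per diameter are segmented; the mean
apparent diameter of the detected central island (the object whose
centroid falls within the island radius plus twice the localization
error) is recorded, and a quadratic $d_{\mathrm{est}}(d_{\mathrm{true}})$
is fitted and inverted on its monotone branch to correct measured means.

Two estimator details matter and are our own choices:

* Grid points where more than 10% of replicate fields yield no detection
  are excluded from the quadratic fit (the points remain in the reported
  table). Their conditional means are selection-biased — only fields
  whose island fluctuated upward are detected — which flattens the low
  end, violates the monotonicity an invertible calibration needs, and
  destabilizes the inversion. The fit is inverse-variance weighted.
* The correction is applied to the **mean** of a measured diameter
  distribution, matching the published usage (apparent mean 59 nm →
  ~33 nm for PALM; 50 nm → ~32 nm for dSTORM); per-island correction is
  available but the calibration is built from means.

**Detectability** is the fraction of fields whose central island is
detected: at 29-nm precision and 0.02 spots/nm², small islands are
increasingly missed (~82% at 30 nm diameter in the published account,
reproduced here within a few percentage points; ≥85–95% at ≥40 nm).
Background false positives — blink clusters of a handful of molecules
passing the 6-localization, 13-nm definition — are a real property of the
method; they are reported, not suppressed, and parameter-recovery tests
therefore match detected objects to ground-truth island positions before
averaging diameters.

The **density factor** 1.45 is selected by rebuilding the zero-error
calibration for candidate factors and minimizing
$\sum_{d = 30,40,\dots,100} (d_{\mathrm{est}} - d)^2 / d^2$; the
selection is reproduced by the acceptance suite over {1.2, 1.45, 2.0}.

# Pair correlation

$g(r)$ is estimated on a 5-nm grid by FFT: the 2-D autocorrelation of the
binned pattern, normalized by density squared and by the autocorrelation
of the mask indicator (exact edge correction for arbitrary mask shapes),
then radially averaged in 10-nm bins with self-pairs removed. The
estimator is unbiased for complete spatial randomness and agrees with a
direct pair-counting oracle within 2%. Island-level analysis computes
$g(r)$ from the localizations inside detected island polygons, per FA,
then averages mean ± SEM across FAs.

The fitted model is $g(r) = 1 + A_1 e^{-r/\xi_1} + A_2 e^{-r/\xi_2}$
with $A_1, A_2 > 0$ and $\xi_1 < \xi_2$; $2\xi_1$ measures the
island-scale diameter and $2\xi_2$ the loose-cluster scale. Start values
are derived from log-linear fits of the tail and of the short-range
residual; a single-exponential fallback is flagged if the two-scale fit
fails. Fits start at $r \ge 10$ nm because repeated localizations of one
fluorophore inflate $g$ below $\sim 2\sigma$. Cross-correlation $c(r)$
uses the same estimator on two channels; its tail ($r > 150$ nm, beyond
the island scale) is fitted with $1 + B e^{-r/\xi}$ — the +1 offset is
included because $c \to 1$ at infinity is physically required — and
$2\xi$ read off as the cluster-scale diameter.

One caution for interpreting recovery tests: for islands placed uniformly
in a hard disk of diameter $D$, the exponential-fit $2\xi_2$ of the
*generated pattern* is substantially smaller than $D$ (the disk's set
covariance is not exponential). Recovery is therefore judged against the
correlation length of the generative process computed by the independent
pair-counting oracle, not against the nominal disk diameter.

# Molecular counting

Copy numbers follow from detections by dividing out blinking overcounting
and the fluorescent fraction and applying an expression scale:
`copies = detections / overcount / fluorescent_fraction x
expression_scale`. Channel presets: mEos3.2 (1.4, 0.60), HMSiR (2.7,
0.90). The median of detections-per-island feeds the island copy number
(the mean is dominated by unresolved merged islands). Worked values
reproduced exactly by the test suite: 36.2 copies/island (T24, 16
detections, x1.9 total-paxillin scale), 26.0 (MEF PALM, 14 detections,
x1/0.64), 33.4 (MEF dSTORM, 13 detections, x1/0.16), 655,000–842,000
copies/cell, and the ~4.1:1 two-channel expression ratio from a 1.4:1
spot-density ratio.

# Hop diffusion

The picket-fence simulator performs a 2-D random walk on a square
compartment lattice of edge $L$; a substep crossing a boundary succeeds
with probability $P$, else the remainder of the step reflects. Defaults:
50 substeps per frame (single-substep displacement « L), 6-kHz frame
rate, 250-ms trajectories, $D_{\mathrm{micro}} = 5\ \mu m^2/s$ — a
field-typical microscopic diffusion coefficient for transmembrane
proteins at ultrafast frame rates; the studied regimes fix $(L, \tau)$ =
(109 nm, 24 ms) outside and (74 nm, 36 ms) inside the FA, with $P$
calibrated to the target residency by a first-order kinetic formula plus
one refinement simulation. Ground-truth compartment residencies are
returned for every trajectory.

Per-trajectory analysis: time-averaged MSD to a quarter of the trajectory
length; hop fit $\mathrm{MSD}(t) = 4\sigma_{\mathrm{off}}^2 +
\frac{L^2}{3}\bigl(1 - e^{-t/\tau_c}\bigr) + 4 D_{\mathrm{MACRO}} t$,
$\tau_c = L^2/(12 D_{\mathrm{micro}})$. Two estimator choices respond to
identifiability limits of this regime:

* At 6 kHz with $L \approx 100$ nm, $\tau_c \approx 0.2$ ms is at the
  first lag, so a free offset is collinear with the plateau; the noise
  offset is fixed to the known localization error (0 in noise-free
  simulations) unless explicitly freed.
* The hop process itself decorrelates over several residency times
  (a walker that has just hopped sits at the boundary and often hops
  straight back), so the jointly fitted linear slope underestimates the
  asymptotic $D_{\mathrm{MACRO}}$; the reported value is the slope of the
  long-lag third of the MSD, with the joint-fit slope kept as
  `D_MACRO_model`. Single-trajectory tail slopes are right-skewed;
  ensemble summaries report both mean and median, and the recovery
  criterion uses the mean. With these choices the simulations recover
  $L$ within ~5–13%, $\tau$ within a few percent, and mean
  $D_{\mathrm{MACRO}}$ within ~10% of the closed form $L^2/(4\tau)$
  (0.124 and 0.038 $\mu m^2/s$ for the two regimes).

**RD classification**: $RD = \mathrm{MSD}(t_N) / (4 D_{2\text{-}4}
t_N)$ at $t_N = N/3$ frames, with $D_{2\text{-}4}$ the short-time
coefficient from MSD lags 2–4. The null is 5,000 simulated Brownian
trajectories matched in length, frame time and noise; trajectories below
the 2.5th percentile are *suppressed*, above the 97.5th *directed*. The
statistic is scale-invariant in $D$ when localization noise is
negligible, so one null serves an ensemble. False positives calibrate to
5% ± 1% by construction; the (109 nm, 24 ms) regime classifies ~85–90%
of trajectories as suppressed. Classification power degrades when the
compartment corner time predates the shortest fitted lag *and* hopping is
fast relative to $t_N$ — at (74 nm, 36 ms) short-lag MSDs are already
compartment-limited, so $D_{2\text{-}4}$ underestimates the free mobility
and RD rises toward 1; this is a property of the statistic at this frame
rate, documented rather than patched.

**Residency lifetimes** are fitted by truncated-exponential maximum
likelihood ($\hat\tau = \overline{t - t_{\min}}$ over $t \ge t_{\min}$,
default two frames; SE $= \hat\tau/\sqrt n$). On finite trajectories
the completed dwells are length-biased — a dwell of length $t$ has only
$T - t$ admissible start times in a window of length $T$ — which
shortens the apparent lifetime by ~10–15% on 250-ms trajectories with
24–36-ms lifetimes; supplying `window_ms` switches to the ML fit under
the corrected density $\propto (T - t)\,e^{-t/\tau}$, which removes the
bias. Distribution comparisons
use the Brunner–Munzel test (implemented here — no installed package
provides it) for sizes and diffusion coefficients, and the log-rank test
(via `survival`, in Suggests) for residency distributions.

# Immobilization mapping

The defining reference for the immobilization criterion is external to
the reproduced account, so the criterion is our design: a maximal run of
≥ `min_duration_frames` positions whose radius of gyration stays below
$k \sigma$ (default $k = 2$) is one event; its circle diameter is
$2(R_g + \sigma)$, anchored to the published scale: a stationary
molecule has $R_g \approx \sqrt2\,\sigma$, giving a 102-nm circle at
21-nm precision against the published 104 nm. Free diffusion at
$0.1\ \mu m^2/s$ triggers events in fewer than 5% of 1-s trajectories at
the published ~0.2-s event-duration scale. Density images are
normalized by the median intensity within the FA mask (thermographic
scale, display-clipped at 0–6 median-multiples); event centers sample the
center pixel (circle-averaging optional — the published account does not
state which, and the center pixel is the less smoothed choice). On
uniformly placed events the fraction above the median is unbiased at 0.5,
so an excess — e.g. the published "over two-thirds" — measures genuine
enrichment.

# End-to-end validation scene

`run_pipeline()` chains the stages on a synthetic FA whose islands have
32-nm true diameter: scene → blinking → merging → segmentation →
calibration → correction → correlation → counting (plus a hop-diffusion
block). Two scene choices make the validation well-posed, and are choices
about the *test*, not about the method:

* Islands are spaced ≥150 nm apart (`min_island_gap`), so every island is
  resolvable; with free overlap (the default elsewhere) nearby islands
  blur into single objects and the corrected mean tests island merging,
  not the correction. The published account flags exactly this confound
  for its own distributions.
* On-times are sub-frame in the validation scene, so each on-event is a
  single localization of precision 29 nm, the level at which the
  calibration is defined. (With multi-frame events, cross-molecule
  merging inside dense islands slightly shrinks apparent islands — a
  real-data effect outside the calibration's model.)

Detected islands are matched to ground-truth positions (best object
within the island radius plus twice the precision) before averaging, and
the corrected mean lands within 15% of 32 nm.

# Problem sizes

Defaults were chosen so the full test suite and the acceptance script
each run in minutes on one core: calibrations use the published 30
fields per diameter; detectability uses 100 fields; hop recovery uses
100 trajectories of 1,500 frames per regime; the RD null uses 5,000
trajectories; correlation scenes hold ~3,500 points each. These sizes
are statements of the validation design, with tolerances set to 2–3
standard errors of the corresponding estimators.

# Known limitations

* The tessellation conventions are a faithful but independent
  reimplementation; absolute island sizes can differ from the original
  software by a few nm at small diameters, which is why size-dependent
  statements are always routed through this package's own calibration.
* The size correction is calibrated for distribution means of resolvable
  islands; unresolved island collections bias apparent sizes upward in
  ways no mean correction can undo.
* The synthetic scenes emulate densities, blinking, blur and geometry,
  not photophysical heterogeneity, drift, sample motion, or
  detection/fitting failures of raw-movie processing (which is upstream
  of this package's inputs).
* Compartment residencies come from simulation ground truth; boundary
  detection from experimental trajectories is out of scope.
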