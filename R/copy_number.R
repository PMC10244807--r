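## Molecular-counting arithmetic: converting localization (on-event)
## counts into molecule copy numbers via the blinking overcount, the
## fluorescent fraction of the tag, and expression-scale factors.

#' Counting factors for copy-number arithmetic
#'
#' @param overcount mean on-events per molecule (1.4 for mEos3.2, 2.7
#'   for HMSiR).
#' @param fluorescent_fraction fraction of tags that are fluorescent /
#'   labelled (0.60 mEos3.2, 0.90 HMSiR).
#' @param expression_scale ratio converting tagged-protein copies to the
#'   target population (e.g. 1.9 for total paxillin in the T24 clone;
#'   1/0.64 for endogenous paxillin from the PALM channel in MEFs;
#'   1/0.16 from the dSTORM channel).
#' @param view_fraction fraction of the membrane captured in the view
#'   field (for per-cell totals).
#' @param recruitment_fraction fraction of expressed molecules recruited
#'   to the imaged membrane (scalar or range).
#' @export
counting_factors <- function(overcount, fluorescent_fraction,
                             expression_scale = 1, view_fraction = 1,
                             recruitment_fraction = 1) {
  stopifnot(overcount > 0, fluorescent_fraction > 0,
            fluorescent_fraction <= 1, expression_scale > 0,
            all(view_fraction > 0), all(view_fraction <= 1),
            all(recruitment_fraction > 0), all(recruitment_fraction <= 1))
  structure(list(overcount = overcount,
                 fluorescent_fraction = fluorescent_fraction,
                 expression_scale = expression_scale,
                 view_fraction = view_fraction,
                 recruitment_fraction = recruitment_fraction),
            class = "counting_factors")
}

#' Channel presets for the two probes
#'
#' @param channel "mEos3.2" (PALM) or "HMSiR" (dSTORM).
#' @return a [counting_factors()] with the probe's overcount and
#'   fluorescent fraction (expression scale 1).
#' @export
counting_preset <- function(channel = c("mEos3.2", "HMSiR")) {
  channel <- match.arg(channel)
  if (channel == "mEos3.2") counting_factors(1.4, 0.60)
  else counting_factors(2.7, 0.90)
}

#' Copies per island from detections per island
#'
#' `copies = detections / overcount / fluorescent_fraction *
#' expression_scale`.  Use the median of the detections-per-island
#' distribution (the mean is dominated by unresolved merged islands).
#'
#' @param detections detections (localizations) per island.
#' @param f a [counting_factors()].
#' @return copy number(s), same length as `detections`.
#' @export
copies_per_island <- function(detections, f) {
  stopifnot(all(detections >= 0))
  detections / f$overcount / f$fluorescent_fraction * f$expression_scale
}

#' Copies per cell from total detections in the view field
#'
#' `copies = total / view_fraction / recruitment_fraction / overcount /
#' fluorescent_fraction`; a range of recruitment fractions yields the
#' printed interval estimates.
#'
#' @param total_detections total detections in the view field.
#' @param f a [counting_factors()] (its `recruitment_fraction` may be a
#'   range, e.g. `c(0.9, 0.7)`).
#' @return copy number(s), one per recruitment fraction.
#' @export
copies_per_cell <- function(total_detections, f) {
  total_detections / f$view_fraction / f$recruitment_fraction /
    f$overcount / f$fluorescent_fraction
}

#' Copy-number ratio of two channels from detected spot densities
#'
#' Each channel's spot density is converted to a molecule density by
#' dividing by its overcount and fluorescent fraction; the result is
#' normalized so channel B equals 1.
#'
#' @param density_ratio spot-density ratio A:B (a single number,
#'   density_A / density_B).
#' @param factors_a,factors_b [counting_factors()] for the two channels.
#' @return list: `ratio` (copies A per copy B), `a`, `b` (the unscaled
#'   per-channel conversion, density / overcount / fluorescent
#'   fraction).
#' @export
expression_ratio_from_spot_densities <- function(density_ratio, factors_a,
                                                 factors_b) {
  stopifnot(density_ratio > 0)
  a <- density_ratio / factors_a$overcount / factors_a$fluorescent_fraction
  b <- 1 / factors_b$overcount / factors_b$fluorescent_fraction
  list(ratio = a / b, a = a, b = b)
}
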