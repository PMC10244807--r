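## Fluorophore photophysics models: stretched-exponential on-periods,
## exponential photon counts, geometric blinking, and the theoretical
## localization-precision formula for EM-gain cameras.

hist_from_input <- function(x, bin_width) {
  ## accept either raw samples or a prepared histogram data.frame(t, count)
  if (is.data.frame(x)) {
    names(x)[1:2] <- c("t", "count")
    return(x)
  }
  breaks <- seq(0, max(x) + bin_width, by = bin_width)
  h <- hist(x, breaks = breaks, plot = FALSE)
  data.frame(t = h$mids, count = h$counts)
}

#' Fit a stretched exponential to an on-period histogram
#'
#' The distribution of fluorescent on-periods (built with 1-frame gap
#' closing, 1-frame-time bins, zero bin excluded) is modelled as
#' `phi(t) = phi0 * exp(-(t / tau)^alpha)` with stretching exponent
#' `alpha` in (0, 1].  Weighted least squares (Poisson weights); the
#' reported SEs are 68.3%-confidence fitting errors.
#'
#' @param on_periods raw on-period durations (ms), or a
#'   `data.frame(t, count)` histogram.
#' @param bin_width histogram bin width in ms (the frame time).
#' @return object of class `stretched_exp_fit`: `phi0, tau, alpha,
#'   se_tau, se_alpha`.
#' @export
fit_stretched_exponential <- function(on_periods, bin_width = 1) {
  h <- hist_from_input(on_periods, bin_width)
  h <- h[h$count > 0 & h$t > 0, ]
  if (nrow(h) < 4)
    stop("stretched-exponential fit refused: fewer than 4 nonzero bins")
  w <- 1 / pmax(h$count, 1)
  start <- list(phi0 = max(h$count),
                tau = sum(h$t * h$count) / sum(h$count), alpha = 0.8)
  fit <- minpack.lm::nlsLM(count ~ phi0 * exp(-(t / tau)^alpha),
                           data = h, start = start, weights = w,
                           lower = c(phi0 = 0, tau = 1e-8, alpha = 1e-3),
                           upper = c(phi0 = Inf, tau = Inf, alpha = 1),
                           control = nls.control(maxiter = 500))
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  structure(list(phi0 = unname(cf["phi0"]), tau = unname(cf["tau"]),
                 alpha = unname(cf["alpha"]),
                 se_tau = unname(se["tau"]), se_alpha = unname(se["alpha"]),
                 fit = fit),
            class = "stretched_exp_fit")
}

#' Fit a single-exponential decay to a photon-count histogram
#'
#' The decay constant of `A * exp(-x / m)` is the mean number of detected
#' photons per on-period.
#'
#' @param photons raw per-event photon counts, or a `data.frame(x, count)`
#'   histogram.
#' @param bin_width histogram bin width (photons); default max/40.
#' @return list of class `exp_photon_fit`: `mean_photons`, `se` (68.3%
#'   confidence).  A warning is raised if the relative SE exceeds 50%.
#' @export
fit_exponential_photons <- function(photons, bin_width = NULL) {
  if (!is.data.frame(photons) && is.null(bin_width))
    bin_width <- max(photons) / 40
  h <- hist_from_input(photons, bin_width %||% 1)
  names(h)[1:2] <- c("x", "count")
  h <- h[h$count > 0, ]
  if (nrow(h) < 4) stop("photon-count fit needs >= 4 nonzero bins")
  start <- list(A = max(h$count),
                m = sum(h$x * h$count) / sum(h$count))
  fit <- minpack.lm::nlsLM(count ~ A * exp(-x / m), data = h,
                           start = start, weights = 1 / pmax(h$count, 1),
                           lower = c(A = 0, m = 1e-8),
                           control = nls.control(maxiter = 500))
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  if (!is.finite(se["m"]) || se["m"] / cf["m"] > 0.5 ||
      cf["m"] > 10 * max(h$x))
    warning("photon-count fit is poorly determined (relative SE > 50% ",
            "or decay constant far beyond the data range)")
  structure(list(mean_photons = unname(cf["m"]), se = unname(se["m"]),
                 fit = fit),
            class = "exp_photon_fit")
}

#' Fit the geometric blinking model to per-molecule detection counts
#'
#' For a monomeric blinking fluorophore the number of on-events per
#' molecule follows `f(N) = p * (1 - p)^(N - 1)`; `p` is the per-event
#' bleaching probability and `1/p` the mean number of detections
#' (overcounting factor).  `p` is estimated by maximum likelihood
#' (`1/mean(N)`, which is also what the printed overcounting arithmetic
#' uses); a chi-square comparison against the geometric pmf is attached
#' as a goodness-of-fit check.
#'
#' @param counts integer detection counts per molecule, all >= 1.
#' @return object of class `geometric_blink_fit`: `p`, `mean_detections
#'   = 1/p` (exactly), `se_p`, and `gof` (chi-square statistic, df,
#'   p-value).
#' @export
fit_geometric_blinking <- function(counts) {
  if (any(counts < 1) || any(counts != round(counts)))
    stop("detection counts must be integers >= 1")
  n <- length(counts)
  m <- mean(counts)
  p <- 1 / m
  ## delta method: se(p) = p^2 * se(mean)
  se_p <- if (n > 1) p^2 * sd(counts) / sqrt(n) else NA_real_
  ## goodness of fit against the geometric pmf (tail pooled)
  tab <- tabulate(counts)
  kmax <- length(tab)
  expd <- n * p * (1 - p)^(seq_len(kmax) - 1)
  expd[kmax] <- n * (1 - p)^(kmax - 1)       # pool the tail
  obs <- tab
  keep <- expd > 0
  chi <- sum((obs[keep] - expd[keep])^2 / expd[keep])
  df <- max(1L, sum(keep) - 2L)
  gof <- list(statistic = chi, df = df,
              p_value = stats::pchisq(chi, df, lower.tail = FALSE))
  structure(list(p = p, mean_detections = m, se_p = se_p, gof = gof,
                 n = n),
            class = "geometric_blink_fit")
}

#' Theoretical localization precision from photon count
#'
#' Mortensen-type maximum-likelihood precision for EM-gain cameras:
#' `sigma^2 = F * (sa^2 / N) * (16/9 + 8 * pi * sa^2 * b^2 / (N * a^2))`
#' with `sa^2 = psf_sd^2 + a^2 / 12`; `F` is the camera excess-noise
#' factor (1.2 for the EM camera used here), `a` the pixel size, `b^2`
#' the background photon variance per pixel.
#'
#' @param photons detected photon count N (vectorized).
#' @param psf_sd PSF Gaussian SD in nm (129 nm for the system modelled).
#' @param pixel pixel size a in nm (55.1).
#' @param background_var background variance per pixel b^2 (photons^2).
#' @param excess_noise excess-noise factor F (>= 1).
#' @return localization SD sigma in nm.
#' @export
localization_precision <- function(photons, psf_sd = 129, pixel = 55.1,
                                   background_var = 0, excess_noise = 1.2) {
  stopifnot(all(photons > 0), excess_noise >= 1)
  sa2 <- psf_sd^2 + pixel^2 / 12
  sig2 <- excess_noise * (sa2 / photons) *
    (16 / 9 + 8 * pi * sa2 * background_var / (photons * pixel^2))
  sqrt(sig2)
}

#' Spot-survival curve
#'
#' Number of detected spots per time bin, normalized to 100% at time 0.
#'
#' @param locs a [loc_table()] (frame-stamped spots).
#' @param window bin width in frames.
#' @return data.frame `t_frame` (bin start frame), `count`, `pct`.
#' @export
spot_survival_curve <- function(locs, window = 1) {
  stopifnot(nrow(locs) > 0, window >= 1)
  f0 <- min(locs$frame)
  bin <- (locs$frame - f0) %/% window
  counts <- tabulate(bin + 1L, nbins = max(bin) + 1L)
  if (counts[1] == 0) stop("empty first time bin: cannot normalize to 100%")
  data.frame(t_frame = (seq_along(counts) - 1L) * window + f0,
             count = counts, pct = 100 * counts / counts[1])
}
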