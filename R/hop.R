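## Trajectory analysis: time-averaged MSD, hop-diffusion model fitting
## (compartment size L, macroscopic diffusion coefficient), RD-based
## motional-mode classification against a Monte-Carlo Brownian null, and
## exponential residency-time fitting.

#' Time-averaged mean-square displacement
#'
#' `MSD(n dt)` averaged over all start times, reported up to a lag of a
#' quarter of the trajectory length.
#'
#' @param traj data.frame `frame, x_nm, y_nm` (fixed frame interval).
#' @param frame_time frame interval in ms.
#' @param max_lag_frac largest lag as a fraction of the length (1/4).
#' @return data.frame `lag, dt_ms, msd, n_pairs` (msd in nm^2).
#' @export
compute_msd <- function(traj, frame_time = 1 / 6, max_lag_frac = 0.25) {
  n <- nrow(traj)
  if (n < 20) stop("trajectory shorter than 20 frames")
  x <- traj$x_nm; y <- traj$y_nm
  lags <- seq_len(max(2L, floor(n * max_lag_frac)))
  msd <- vapply(lags, function(k) {
    dx <- x[(k + 1):n] - x[1:(n - k)]
    dy <- y[(k + 1):n] - y[1:(n - k)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  data.frame(lag = lags, dt_ms = lags * frame_time, msd = msd,
             n_pairs = n - lags)
}

#' Hop-diffusion fit of an MSD curve
#'
#' Confined-plus-hop model:
#' `MSD(t) = 4 sigma_off^2 + (L^2 / 3) (1 - exp(-t / tau_c)) +
#' 4 D_MACRO t`, with `tau_c = L^2 / (12 D_micro)`.  The plateau term is
#' the stationary MSD of a square compartment of edge L; the linear term
#' is the long-time intercompartmental diffusion.
#'
#' At fast frame rates the compartment corner time
#' `tau_c = L^2 / (12 D_micro)` can be comparable to one frame, in which
#' case a free offset is not identifiable from the plateau; the noise
#' offset is therefore fixed to the known localization error by default
#' (0 for noise-free simulations) and only fitted freely when
#' `sigma_off = NULL`.
#'
#' @param msd result of [compute_msd()].
#' @param sigma_off known localization error SD (nm), fixed in the fit;
#'   NULL to fit it freely.
#' @return object of class `hop_fit_result`: `L` (nm), `D_micro`,
#'   `D_MACRO` (um^2/s, from the long-lag tail slope; the jointly
#'   fitted slope is kept as `D_MACRO_model`), `sigma_off` (nm), `rss`,
#'   `converged`.
#' @export
hop_fit <- function(msd, sigma_off = 0) {
  d <- msd[is.finite(msd$msd), ]
  ## starts: tail slope -> D_MACRO; early slope -> D_micro; plateau -> L
  nt <- nrow(d)
  tail_idx <- d$dt_ms >= quantile(d$dt_ms, 0.5)
  tail_fit <- lm(msd ~ dt_ms, data = d[tail_idx, ])
  dmac0 <- max(coef(tail_fit)[2] / 4, 1e-4)
  early <- d[seq_len(min(4, nt)), ]
  dmic0 <- max((early$msd[nrow(early)] - early$msd[1]) /
                 (4 * (early$dt_ms[nrow(early)] - early$dt_ms[1])), dmac0)
  L0 <- sqrt(3 * max(coef(tail_fit)[1], 300))
  fit <- if (is.null(sigma_off)) tryCatch(
    minpack.lm::nlsLM(
      msd ~ 4 * s2 + (L^2 / 3) * (1 - exp(-12 * Dmic * dt_ms / L^2)) +
        4 * Dmac * dt_ms,
      data = d,
      start = list(s2 = 400, L = L0, Dmic = dmic0, Dmac = dmac0),
      lower = c(s2 = 0, L = 1, Dmic = 1e-6, Dmac = 0),
      control = nls.control(maxiter = 1000)),
    error = function(e) NULL)
  else tryCatch(
    minpack.lm::nlsLM(
      msd ~ 4 * sigma_off^2 + (L^2 / 3) *
        (1 - exp(-12 * Dmic * dt_ms / L^2)) + 4 * Dmac * dt_ms,
      data = cbind(d, sigma_off = sigma_off),
      start = list(L = L0, Dmic = dmic0, Dmac = dmac0),
      lower = c(L = 1, Dmic = 1e-6, Dmac = 0),
      control = nls.control(maxiter = 1000)),
    error = function(e) NULL)
  ## the tail slope needs no model fit, so it is reported even when
  ## the confinement fit fails (dropping those trajectories would
  ## selectively discard fast-diffusing ones and bias ensemble means)
  tmax0 <- max(d$dt_ms)
  tail_d0 <- d[d$dt_ms >= tmax0 / 3, ]
  dmac_tail0 <- unname(coef(lm(msd ~ dt_ms, data = tail_d0))[2]) / 4
  if (is.null(fit))
    return(structure(list(L = NA_real_, D_micro = NA_real_,
                          D_MACRO = max(dmac_tail0, 0) / 1000,
                          D_MACRO_model = NA_real_,
                          sigma_off = NA_real_,
                          rss = NA_real_, converged = FALSE),
                     class = "hop_fit_result"))
  cf <- coef(fit)
  s_out <- if (is.null(sigma_off)) sqrt(max(unname(cf["s2"]), 0))
           else sigma_off
  ## D_MACRO from the long-lag linear regime ([tmax/3, tmax]): the
  ## additive model books the crossover of the hop random walk (whose
  ## own relaxation spans several residency times) into its linear
  ## term, biasing the jointly fitted slope low; the tail slope is the
  ## asymptotic intercompartmental diffusion coefficient
  dmac_tail <- dmac_tail0
  structure(list(L = unname(cf["L"]),
                 D_micro = unname(cf["Dmic"]) / 1000,   # nm^2/ms -> um^2/s
                 D_MACRO = max(dmac_tail, 0) / 1000,
                 D_MACRO_model = unname(cf["Dmac"]) / 1000,
                 sigma_off = s_out,
                 rss = sum(stats::residuals(fit)^2), converged = TRUE,
                 fit = fit),
            class = "hop_fit_result")
}

## short-time diffusion coefficient from MSD lags 2-4 (linear fit with
## free offset, slope / 4)
d24_from_msd <- function(msd) {
  d <- msd[msd$lag %in% 2:4, ]
  unname(coef(lm(msd ~ dt_ms, data = d))[2]) / 4
}

rd_statistic_from_msd <- function(msd, n_frames, lag_frac = 1 / 3) {
  lagN <- max(2L, round(n_frames * lag_frac))
  lagN <- min(lagN, max(msd$lag))
  d24 <- d24_from_msd(msd)
  if (!is.finite(d24) || d24 <= 0) return(NA_real_)
  tN <- msd$dt_ms[msd$lag == lagN]
  msd$msd[msd$lag == lagN] / (4 * d24 * tN)
}

#' RD statistic of one trajectory
#'
#' Relative deviation from ideal Brownian motion:
#' `RD = MSD(t_N) / (4 D_2-4 t_N)` at the fixed fractional lag
#' `t_N = round(N / 3)` frames, where `D_2-4` is the short-time
#' diffusion coefficient from MSD lags 2-4.
#'
#' @param traj data.frame `frame, x_nm, y_nm`.
#' @param frame_time frame interval (ms).
#' @param lag_frac fractional lag (default 1/3).
#' @return the RD value (NA when D_2-4 <= 0).
#' @export
rd_statistic <- function(traj, frame_time = 1 / 6, lag_frac = 1 / 3) {
  ## RD uses a lag beyond the MSD default quarter-length window
  msd <- compute_msd(traj, frame_time, max_lag_frac = min(0.5, lag_frac + 0.1))
  rd_statistic_from_msd(msd, nrow(traj), lag_frac)
}

#' Monte-Carlo Brownian null distribution of RD
#'
#' Simulates `n_traj` simple-Brownian trajectories with matched
#' diffusion coefficient, length, frame time and localization noise and
#' computes their RD values; the 2.5th and 97.5th percentiles are the
#' suppressed/directed classification bounds.
#'
#' @param n_frames trajectory length (frames).
#' @param frame_time frame interval (ms).
#' @param D diffusion coefficient (um^2/s).
#' @param loc_sigma localization noise SD (nm).
#' @param n_traj ensemble size (5000).
#' @param lag_frac RD lag fraction.
#' @param seed integer seed (optional).
#' @return object of class `rd_null`: `rd` (samples), `rd_min`,
#'   `rd_max` (2.5/97.5 percentiles), parameters.
#' @export
rd_null_distribution <- function(n_frames, frame_time = 1 / 6, D = 5,
                                 loc_sigma = 0, n_traj = 5000,
                                 lag_frac = 1 / 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D_nm2_ms <- D * 1000
  step_sd <- sqrt(2 * D_nm2_ms * frame_time)
  lags <- c(2L, 3L, 4L, max(2L, round(n_frames * lag_frac)))
  chunk <- max(1L, floor(2e6 / n_frames))
  rd <- numeric(0)
  done <- 0L
  while (done < n_traj) {
    m <- min(chunk, n_traj - done)
    X <- matrix(rnorm(m * n_frames, 0, step_sd), m, n_frames)
    Y <- matrix(rnorm(m * n_frames, 0, step_sd), m, n_frames)
    X <- t(apply(X, 1, cumsum)); Y <- t(apply(Y, 1, cumsum))
    if (loc_sigma > 0) {
      X <- X + matrix(rnorm(m * n_frames, 0, loc_sigma), m, n_frames)
      Y <- Y + matrix(rnorm(m * n_frames, 0, loc_sigma), m, n_frames)
    }
    msd_at <- function(k) {
      dx <- X[, (k + 1):n_frames, drop = FALSE] -
        X[, 1:(n_frames - k), drop = FALSE]
      dy <- Y[, (k + 1):n_frames, drop = FALSE] -
        Y[, 1:(n_frames - k), drop = FALSE]
      rowMeans(dx^2 + dy^2)
    }
    msds <- vapply(lags, msd_at, numeric(m))
    msds <- matrix(msds, nrow = m)
    t24 <- lags[1:3] * frame_time
    ## slope of lsq line through the three short-time points
    sl <- apply(msds[, 1:3, drop = FALSE], 1, function(z)
      sum((t24 - mean(t24)) * (z - mean(z))) / sum((t24 - mean(t24))^2))
    d24 <- sl / 4
    tN <- lags[4] * frame_time
    rd_chunk <- msds[, 4] / (4 * d24 * tN)
    rd_chunk[d24 <= 0] <- NA
    rd <- c(rd, rd_chunk)
    done <- done + m
  }
  structure(list(rd = rd,
                 rd_min = unname(quantile(rd, 0.025, na.rm = TRUE)),
                 rd_max = unname(quantile(rd, 0.975, na.rm = TRUE)),
                 n_frames = n_frames, frame_time = frame_time, D = D,
                 loc_sigma = loc_sigma, lag_frac = lag_frac),
            class = "rd_null")
}

#' Classify the motional mode of a trajectory
#'
#' Suppressed if RD < RD_min (2.5th percentile of the Brownian null),
#' directed if RD > RD_MAX (97.5th), simple otherwise.  The null must be
#' matched in length and frame time; RD is scale-invariant in D when
#' localization noise is negligible, so one null serves an ensemble.
#'
#' @param traj data.frame `frame, x_nm, y_nm`.
#' @param null an [rd_null_distribution()] result; computed on the fly
#'   (matched D, 5000 trajectories) when NULL.
#' @param frame_time frame interval (ms).
#' @param lag_frac RD lag fraction.
#' @return object of class `rd_classification`: `RD`, `rd_min`,
#'   `rd_max`, `mode` ("suppressed", "simple", "directed", or
#'   "unclassifiable").
#' @export
rd_classify <- function(traj, null = NULL, frame_time = 1 / 6,
                        lag_frac = 1 / 3) {
  msd <- compute_msd(traj, frame_time,
                     max_lag_frac = min(0.5, lag_frac + 0.1))
  rd <- rd_statistic_from_msd(msd, nrow(traj), lag_frac)
  if (is.null(null)) {
    d24 <- d24_from_msd(msd)                 # nm^2/ms
    null <- rd_null_distribution(nrow(traj), frame_time,
                                 D = max(d24, 1e-3) / 1000,  # -> um^2/s
                                 n_traj = 5000, lag_frac = lag_frac)
  }
  mode <- if (!is.finite(rd)) "unclassifiable"
          else if (rd < null$rd_min) "suppressed"
          else if (rd > null$rd_max) "directed"
          else "simple"
  structure(list(RD = rd, rd_min = null$rd_min, rd_max = null$rd_max,
                 mode = mode),
            class = "rd_classification")
}

#' Exponential fit of compartment residency times
#'
#' Maximum-likelihood exponential lifetime with left truncation below
#' `t_min` (dwells shorter than two frames are unobservable):
#' `tau_hat = mean(t - t_min)` over dwells >= t_min, SE = tau / sqrt(n)
#' (68.3% confidence).  When the right-censored first/last dwells of
#' finite trajectories are supplied, the censored-exponential MLE
#' `tau_hat = (sum of event excess times + sum of censored times) /
#' (number of events)` is used instead — on trajectories only ~10
#' lifetimes long, ignoring censoring biases the lifetime low because
#' the longest dwells are the ones cut off.
#'
#' @param times completed residency times (ms), e.g. simulator ground
#'   truth (`attr(traj, "dwell_ms")`).
#' @param t_min truncation threshold (ms); default two frame times.
#' @param frame_time frame interval (ms), used for the default `t_min`.
#' @param censored optional right-censored dwell durations (ms),
#'   e.g. `attr(traj, "censored_ms")`; used for the censored-exponential
#'   MLE when `window_ms` is not given.
#' @param window_ms optional trajectory duration (ms).  A completed
#'   dwell of length t can only be observed if it fits inside the
#'   window, with `window_ms - t` admissible start times, so on short
#'   trajectories the sample is length-biased against long dwells; when
#'   the window is supplied the ML fit uses the corrected density
#'   proportional to `(window_ms - t) exp(-t / tau)`.
#' @return list of class `residency_fit`: `tau`, `se_tau`, `n`.
#' @export
fit_residency_times <- function(times, t_min = NULL, frame_time = 1 / 6,
                                censored = NULL, window_ms = NULL) {
  if (is.null(t_min)) t_min <- 2 * frame_time
  t <- times[times >= t_min]
  if (length(t) < 10) stop("fewer than 10 usable residency times")
  if (sd(t) == 0) warning("degenerate residency-time sample (all equal)")
  if (!is.null(window_ms)) {
    T_w <- window_ms
    t <- t[t < T_w]
    nll <- function(tau) {
      z <- stats::integrate(function(u) (T_w - u) * exp(-u / tau),
                            t_min, T_w)$value
      -sum(-t / tau) + length(t) * log(z)
    }
    tau <- stats::optimize(nll, c(frame_time, 50 * mean(t)))$minimum
  } else if (!is.null(censored)) {
    tau <- (sum(t - t_min) + sum(censored)) / length(t)
  } else {
    tau <- mean(t - t_min)
  }
  structure(list(tau = tau, se_tau = tau / sqrt(length(t)),
                 n = length(t), t_min = t_min),
            class = "residency_fit")
}

#' Brunner-Munzel test
#'
#' Nonparametric test for stochastic equality of two samples (used for
#' comparing compartment-size and D_MACRO distributions between
#' conditions).  Two-sided, with the t-approximation of the BM
#' statistic.
#'
#' @param x,y numeric samples.
#' @return list: `statistic`, `df`, `p_value`, `p_hat` (estimated
#'   P(X < Y) + 0.5 P(X = Y)).
#' @export
brunner_munzel_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r_all <- rank(c(x, y))
  rx <- r_all[seq_len(nx)]; ry <- r_all[nx + seq_len(ny)]
  mx <- mean(rx); my <- mean(ry)
  p_hat <- (my - (ny + 1) / 2) / nx
  rxi <- rank(x); ryi <- rank(y)
  sx2 <- sum((rx - rxi - mx + (nx + 1) / 2)^2) / (nx - 1)
  sy2 <- sum((ry - ryi - my + (ny + 1) / 2)^2) / (ny - 1)
  se <- sqrt(nx * ny * (sx2 / (nx * ny^2) + sy2 / (ny * nx^2)))
  stat <- (my - mx) / (sqrt(nx + ny) * se) * sqrt(nx * ny / (nx + ny))
  df <- (sx2 / ny + sy2 / nx)^2 /
    ((sx2 / ny)^2 / (nx - 1) + (sy2 / nx)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  list(statistic = stat, df = df, p_value = p, p_hat = p_hat)
}

#' Summarize hop-diffusion fits for an ensemble of trajectories
#'
#' @param trajs list of trajectories.
#' @param frame_time frame interval (ms).
#' @param null optional shared [rd_null_distribution()].
#' @return list: `per_trajectory` data.frame (L, D_micro, D_MACRO, RD,
#'   mode), `medians`, `suppressed_fraction`.
#' @export
hop_ensemble_summary <- function(trajs, frame_time = 1 / 6, null = NULL) {
  rows <- lapply(trajs, function(tr) {
    msd <- compute_msd(tr, frame_time)
    hf <- hop_fit(msd)
    cl <- rd_classify(tr, null = null, frame_time = frame_time)
    data.frame(L = hf$L, D_micro = hf$D_micro, D_MACRO = hf$D_MACRO,
               RD = cl$RD, mode = cl$mode, converged = hf$converged)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$converged & is.finite(tab$L)
  list(per_trajectory = tab,
       medians = c(L = median(tab$L[ok]),
                   D_MACRO = median(tab$D_MACRO[ok]),
                   D_micro = median(tab$D_micro[ok])),
       means = c(L = mean(tab$L[ok]),
                 D_MACRO = mean(tab$D_MACRO[ok])),
       suppressed_fraction = mean(tab$mode == "suppressed", na.rm = TRUE))
}
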