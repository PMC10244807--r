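## Pair auto- and cross-correlation of localization patterns inside a
## mask, computed with FFTs so that arbitrary boundary shapes are
## edge-corrected exactly: the pair-count image is normalized by the
## autocorrelation of the mask indicator (the discrete set covariance).

## rasterize points and mask on a common grid
corr_grids <- function(xy_list, mask, grid) {
  if (is.list(mask) && !is.null(mask$x)) {
    bx <- range(mask$x); by <- range(mask$y)
  } else {
    bx <- mask[1:2]; by <- mask[3:4]
  }
  nx <- ceiling((bx[2] - bx[1]) / grid)
  ny <- ceiling((by[2] - by[1]) / grid)
  ## mask indicator sampled at cell centers
  cx <- bx[1] + (seq_len(nx) - 0.5) * grid
  cy <- by[1] + (seq_len(ny) - 0.5) * grid
  W <- if (is.list(mask) && !is.null(mask$x)) {
    gx <- rep(cx, each = ny); gy <- rep(cy, nx)
    matrix(point_in_poly(gx, gy, mask), nrow = ny)
  } else matrix(TRUE, ny, nx)
  H <- lapply(xy_list, function(xy) {
    ix <- floor((xy[, 1] - bx[1]) / grid) + 1L
    iy <- floor((xy[, 2] - by[1]) / grid) + 1L
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    ix <- ix[ok]; iy <- iy[ok]
    h <- matrix(0, ny, nx)
    for (k in seq_along(ix)) h[iy[k], ix[k]] <- h[iy[k], ix[k]] + 1
    keep <- W[cbind(iy, ix)]
    h[!W] <- 0   # points outside the mask are discarded
    h
  })
  list(H = H, W = W * 1, grid = grid, ny = ny, nx = nx)
}

## 2-D circular cross-correlation via FFT, zero-padded to linear
xcorr2 <- function(A, B) {
  ny <- nrow(A); nx <- ncol(A)
  py <- stats::nextn(2 * ny, c(2, 3)); px <- stats::nextn(2 * nx, c(2, 3))
  Ap <- matrix(0, py, px); Ap[1:ny, 1:nx] <- A
  Bp <- matrix(0, py, px); Bp[1:ny, 1:nx] <- B
  C <- Re(fft(Conj(fft(Ap)) * fft(Bp), inverse = TRUE)) / (py * px)
  ## displacement (dy, dx) in [-(ny-1), ny-1] x [-(nx-1), nx-1]
  list(C = C, py = py, px = px)
}

radial_accumulate <- function(C, M, grid, py, px, r_max, bin_width, rho2) {
  dy <- c(0:(py / 2), -((py - 1) %/% 2):-1)
  dx <- c(0:(px / 2), -((px - 1) %/% 2):-1)
  R <- sqrt(outer(dy^2, dx^2, "+")) * grid
  bins <- floor(R / bin_width) + 1L
  nb <- ceiling(r_max / bin_width)
  sel <- bins <= nb & M > 1e-9
  num <- tapply(C[sel], bins[sel], sum)
  den <- tapply(M[sel], bins[sel], sum)
  r_mid <- (as.integer(names(num)) - 0.5) * bin_width
  g <- as.numeric(num) / (rho2 * grid^4 * as.numeric(den))
  data.frame(r = r_mid, g = g, pair_weight = as.numeric(num))
}

#' Pair autocorrelation g(r) of a point pattern in a mask
#'
#' `g(r)` is estimated as the radially averaged 2-D autocorrelation of
#' the binned point pattern, normalized by the density squared and by
#' the autocorrelation of the mask indicator (exact edge correction for
#' complex boundary shapes).  Unbiased for complete spatial randomness
#' (g = 1); self-pairs are removed.
#'
#' @param points two-column matrix or data.frame of positions (nm), or a
#'   [loc_table()].
#' @param mask either a polygon `list(x, y)` or a rectangle
#'   `c(xmin, xmax, ymin, ymax)`.
#' @param r_max maximum displacement (nm); truncated to the mask extent
#'   with a warning if larger.
#' @param bin_width radial bin width (nm).
#' @param grid histogram cell size (nm).
#' @return data.frame `r, g, pair_weight` of class `pair_correlation`.
#' @export
pair_autocorrelation <- function(points, mask, r_max = 800, bin_width = 10,
                                 grid = 5) {
  xy <- as_xy(points)
  if (nrow(xy) < 50) stop("need at least 50 points inside the mask")
  gr <- corr_grids(list(xy), mask, grid)
  ext <- max(dim(gr$W)) * grid
  if (r_max > ext) {
    warning("r_max beyond the mask extent; truncating")
    r_max <- ext
  }
  H <- gr$H[[1]]
  n <- sum(H)
  area <- sum(gr$W) * grid^2
  rho <- n / area
  cc <- xcorr2(H, H)
  cc$C[1, 1] <- cc$C[1, 1] - n          # remove self-pairs
  mm <- xcorr2(gr$W, gr$W)
  out <- radial_accumulate(cc$C, mm$C, grid, cc$py, cc$px, r_max,
                           bin_width, rho^2)
  class(out) <- c("pair_correlation", "data.frame")
  attr(out, "n_points") <- n
  out
}

#' Pair cross-correlation c(r) of two point patterns in one mask
#'
#' Same estimator as [pair_autocorrelation()] with the cross-histogram;
#' approximately 1 everywhere for independent patterns.
#'
#' @param points_a,points_b the two patterns.
#' @inheritParams pair_autocorrelation
#' @return data.frame `r, g, pair_weight` (g holds c(r)).
#' @export
pair_crosscorrelation <- function(points_a, points_b, mask, r_max = 800,
                                  bin_width = 10, grid = 5) {
  xya <- as_xy(points_a); xyb <- as_xy(points_b)
  if (nrow(xya) < 50 || nrow(xyb) < 50)
    stop("need at least 50 points in each pattern")
  gr <- corr_grids(list(xya, xyb), mask, grid)
  ext <- max(dim(gr$W)) * grid
  if (r_max > ext) {
    warning("r_max beyond the mask extent; truncating")
    r_max <- ext
  }
  Ha <- gr$H[[1]]; Hb <- gr$H[[2]]
  na <- sum(Ha); nb <- sum(Hb)
  area <- sum(gr$W) * grid^2
  cc <- xcorr2(Ha, Hb)
  mm <- xcorr2(gr$W, gr$W)
  out <- radial_accumulate(cc$C, mm$C, grid, cc$py, cc$px, r_max,
                           bin_width, (na / area) * (nb / area))
  class(out) <- c("pair_correlation", "data.frame")
  attr(out, "n_points") <- c(na, nb)
  out
}

as_xy <- function(p) {
  if (is.data.frame(p)) {
    if (!is.null(p$x_nm)) cbind(p$x_nm, p$y_nm) else cbind(p[[1]], p[[2]])
  } else as.matrix(p)
}

#' Average correlation curves across focal adhesions
#'
#' @param curves list of `pair_correlation` data.frames on a common r
#'   grid.
#' @return data.frame `r, g, sem` (mean and SEM across curves).
#' @export
average_correlation <- function(curves) {
  r <- curves[[1]]$r
  G <- vapply(curves, function(cv) cv$g[match(r, cv$r)],
              numeric(length(r)))
  G <- matrix(G, nrow = length(r))
  data.frame(r = r,
             g = rowMeans(G, na.rm = TRUE),
             sem = apply(G, 1, function(z)
               sd(z, na.rm = TRUE) / sqrt(sum(is.finite(z)))))
}

#' Fit the two-exponential model to g(r)
#'
#' `g(r) = 1 + A1 * exp(-r / xi1) + A2 * exp(-r / xi2)` with A1, A2 > 0
#' and `xi1 < xi2` by convention; `2 * xi1` measures the island-scale
#' diameter and `2 * xi2` the loose-cluster diameter.  Weighted least
#' squares when SEMs are available.  If the two-exponential fit fails to
#' converge a single-exponential fallback is returned, flagged.
#'
#' @param corr data.frame with `r`, `g` and optionally `sem`.
#' @param r_min smallest r included (default 10 nm: below ~2 sigma,
#'   repeated localizations of one fluorophore dominate g).
#' @param start optional named start list.
#' @return object of class `correlation_fit`: `A1, xi1, A2, xi2`, SEs,
#'   `diameters` (2 xi1, 2 xi2), `single_exp_fallback` flag.
#' @export
fit_g_two_exponential <- function(corr, r_min = 10, start = NULL) {
  d <- corr[corr$r >= r_min & is.finite(corr$g), ]
  w <- if (!is.null(d$sem) && all(is.finite(d$sem)) && all(d$sem > 0))
    1 / d$sem^2 else rep(1, nrow(d))
  if (max(d$g) - 1 < 1e-3) {
    ## structureless input: both amplitudes are zero by inspection
    return(structure(list(A1 = 0, xi1 = NA_real_, A2 = 0, xi2 = NA_real_,
                          se = NULL, diameters = c(island = NA_real_,
                                                   cluster = NA_real_),
                          single_exp_fallback = TRUE, fit = NULL),
                     class = "correlation_fit"))
  }
  if (is.null(start)) {
    ## data-driven starts: log-linear tail fit seeds the slow
    ## component, the short-range residual seeds the fast one
    b <- pmax(d$g - 1, 1e-6)
    tail_sel <- d$r >= min(150, max(d$r) / 2) & b > 1e-4
    xi2_0 <- 150; A2_0 <- 0.01
    if (sum(tail_sel) >= 4) {
      tf <- lm(log(b[tail_sel]) ~ d$r[tail_sel])
      if (is.finite(coef(tf)[2]) && coef(tf)[2] < 0) {
        xi2_0 <- min(max(-1 / coef(tf)[2], 20), 2000)
        A2_0 <- max(exp(coef(tf)[1]), 1e-3)
      }
    }
    res <- pmax(b - A2_0 * exp(-d$r / xi2_0), 1e-6)
    head_sel <- d$r <= max(80, 3 * d$r[1])
    xi1_0 <- 25; A1_0 <- max(res[1], 0.05)
    if (sum(head_sel) >= 3) {
      hf <- lm(log(res[head_sel]) ~ d$r[head_sel])
      if (is.finite(coef(hf)[2]) && coef(hf)[2] < 0) {
        xi1_0 <- min(max(-1 / coef(hf)[2], 2), xi2_0)
        A1_0 <- max(exp(coef(hf)[1]), 0.05)
      }
    }
    start <- list(A1 = A1_0, xi1 = xi1_0, A2 = A2_0, xi2 = xi2_0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ 1 + A1 * exp(-r / xi1) + A2 * exp(-r / xi2),
                      data = d, start = start, weights = w,
                      lower = c(A1 = 0, xi1 = 1, A2 = 0, xi2 = 1),
                      control = nls.control(maxiter = 1000)),
    error = function(e) NULL)
  fallback <- FALSE
  if (is.null(fit)) {
    fallback <- TRUE
    fit <- minpack.lm::nlsLM(g ~ 1 + A1 * exp(-r / xi1), data = d,
                             start = start[c("A1", "xi1")], weights = w,
                             lower = c(A1 = 0, xi1 = 1),
                             control = nls.control(maxiter = 1000))
  }
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (!fallback && cf["xi1"] > cf["xi2"]) {   # enforce xi1 < xi2
    cf <- cf[c("A2", "xi2", "A1", "xi1")]
    se <- se[c("A2", "xi2", "A1", "xi1")]
    names(cf) <- names(se) <- c("A1", "xi1", "A2", "xi2")
  }
  structure(list(A1 = unname(cf["A1"]), xi1 = unname(cf["xi1"]),
                 A2 = unname(if (fallback) NA else cf["A2"]),
                 xi2 = unname(if (fallback) NA else cf["xi2"]),
                 se = se,
                 diameters = c(island = 2 * unname(cf["xi1"]),
                               cluster = if (fallback) NA
                                         else 2 * unname(cf["xi2"])),
                 single_exp_fallback = fallback, fit = fit),
            class = "correlation_fit")
}

#' Fit the tail of c(r) with a single exponential
#'
#' `c(r) = 1 + B * exp(-r / xi)` fitted for `r > r_min` (150 nm, beyond
#' the island scale), so the correlation length reflects the
#' island-cluster scale; reports `2 * xi`.
#'
#' @param corr data.frame with `r`, `g` (holding c) and optionally `sem`.
#' @param r_min lower fit bound (nm).
#' @return list of class `tail_fit`: `B, xi, two_xi, se`, `flat_tail`
#'   flag (set when the tail carries no decaying signal).
#' @export
fit_c_tail_exponential <- function(corr, r_min = 150) {
  d <- corr[corr$r > r_min & is.finite(corr$g), ]
  if (nrow(d) < 4) stop("c(r) not defined beyond r_min")
  w <- if (!is.null(d$sem) && all(is.finite(d$sem)) && all(d$sem > 0))
    1 / d$sem^2 else rep(1, nrow(d))
  if (max(d$g) - 1 < 1e-3) {
    ## no decaying signal at all: nothing to fit
    warning("flat c(r) tail: correlation length unbounded")
    return(structure(list(B = 0, xi = NA_real_, two_xi = NA_real_,
                          se = c(B = NA, xi = NA), flat_tail = TRUE,
                          fit = NULL),
                     class = "tail_fit"))
  }
  b0 <- max(mean(d$g[seq_len(3)]) - 1, 0.01)
  fit <- minpack.lm::nlsLM(g ~ 1 + B * exp(-r / xi), data = d,
                           start = list(B = b0, xi = 150), weights = w,
                           lower = c(B = 0, xi = 1),
                           upper = c(B = Inf, xi = 1e6),
                           control = nls.control(maxiter = 1000))
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  flat <- cf["B"] < 1e-3 || cf["xi"] > 1e5 ||
    (is.finite(se["xi"]) && se["xi"] > 10 * cf["xi"])
  if (flat) warning("flat c(r) tail: correlation length unbounded")
  structure(list(B = unname(cf["B"]), xi = unname(cf["xi"]),
                 two_xi = 2 * unname(cf["xi"]), se = se,
                 flat_tail = unname(flat), fit = fit),
            class = "tail_fit")
}

#' Autocorrelation of island localizations per FA, then averaged
#'
#' Correlation input is restricted to the localizations inside detected
#' island polygons, computed per FA (the FA's bounding box serves as
#' the mask via the island-membership restriction) and averaged as
#' mean +/- SEM across FAs.
#'
#' @param seg a `segmentation_result` from [segment_fa_and_islands()]
#'   (the member coordinates live in its tessellation).
#' @param ... passed to [pair_autocorrelation()].
#' @return list: `mean` (data.frame r, g, sem), `per_fa` (list of
#'   curves).
#' @export
fa_island_autocorrelation <- function(seg, ...) {
  stopifnot(inherits(seg, "segmentation_result"))
  if (is.null(seg$islands)) stop("segmentation contains no islands")
  vd <- seg$voronoi
  curves <- list()
  for (fa_id in unique(seg$islands$fa_id)) {
    isl <- seg$islands[seg$islands$fa_id == fa_id, ]
    mem <- unlist(isl$members)
    if (length(mem) < 50) next
    fa_mem <- seg$fa$members[[which(seg$fa$object == fa_id)]]
    pad <- 50
    mask <- c(range(vd$x[fa_mem]) + c(-pad, pad),
              range(vd$y[fa_mem]) + c(-pad, pad))
    curves[[length(curves) + 1]] <-
      pair_autocorrelation(cbind(vd$x[mem], vd$y[mem]), mask, ...)
  }
  if (!length(curves)) stop("no FA with enough island localizations")
  list(mean = average_correlation(curves), per_fa = curves)
}
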