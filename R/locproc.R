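## Post-processing of raw localizations: gap closing / merging of
## per-frame spots into on-events, grouping of on-events into molecules,
## and Gaussian rendering of super-resolved / diffraction-limited images.

#' Merging configuration
#'
#' @param max_off_frames maximum number of dark frames bridged when
#'   merging per-frame localizations of one on-event (1-frame gap
#'   closing by default).
#' @param max_distance spatial search cutoff in nm (see
#'   [merge_cutoff_distance()]).
#' @param cutoff_time molecule-grouping time cutoff in seconds (3 s for
#'   mEos3.2, 10 s for HMSiR).
#' @export
merge_config <- function(max_off_frames = 1, max_distance = 82,
                         cutoff_time = 3) {
  stopifnot(max_distance > 0, max_off_frames >= 0, cutoff_time > 0)
  structure(list(max_off_frames = max_off_frames,
                 max_distance = max_distance, cutoff_time = cutoff_time),
            class = "merge_config")
}

#' Merging / grouping cutoff distance
#'
#' The cutoff distance applied when deciding whether two localizations
#' belong to the same emitter is `k * sqrt(2) * sigma`, rounded to the
#' nearest nm: each of the two positions carries an error of SD `sigma`,
#' so their separation has SD `sqrt(2) * sigma`, and `k` (2 for PALM,
#' 3 for dSTORM) sets the acceptance quantile.  This reproduces the two
#' standard values: `2 * sqrt(2) * 29 = 82` nm and
#' `3 * sqrt(2) * 19 = 81` nm.
#'
#' @param sigma mean localization precision (nm).
#' @param k multiplier, 2 or 3.
#' @return cutoff in nm (integer-rounded).
#' @export
merge_cutoff_distance <- function(sigma, k) {
  stopifnot(sigma > 0, k %in% c(2, 3))
  round(k * sqrt(2) * sigma)
}

## Greedy frame-ordered nearest-neighbour linking.
## events: running matrix of open tracks with columns
##   last_frame, x, y, w (photon weight), plus accumulators.
## Ties are broken by smaller distance, then lower index.
link_frames <- function(frame, x, y, photons, max_gap_frames, max_distance) {
  n <- length(frame)
  track <- integer(n)
  ord <- order(frame, seq_len(n))
  frames_u <- unique(frame[ord])
  ## open-track state
  t_last <- numeric(0); t_x <- numeric(0); t_y <- numeric(0)
  n_tracks <- 0L
  idx_by_frame <- split(ord, frame[ord])
  for (f in frames_u) {
    ii <- idx_by_frame[[as.character(f)]]
    active <- which(t_last >= f - max_gap_frames - 1 & t_last < f)
    assigned_loc <- rep(FALSE, length(ii))
    if (length(active)) {
      ## all candidate pairs within cutoff, greedy by distance
      dx <- outer(x[ii], t_x[active], "-")
      dy <- outer(y[ii], t_y[active], "-")
      d <- sqrt(dx^2 + dy^2)
      cand <- which(d <= max_distance, arr.ind = TRUE)
      if (nrow(cand)) {
        o <- order(d[cand], cand[, 2], cand[, 1])
        cand <- cand[o, , drop = FALSE]
        used_track <- rep(FALSE, length(active))
        for (r in seq_len(nrow(cand))) {
          li <- cand[r, 1]; tj <- cand[r, 2]
          if (assigned_loc[li] || used_track[tj]) next
          assigned_loc[li] <- TRUE; used_track[tj] <- TRUE
          tr <- active[tj]
          track[ii[li]] <- tr
          t_last[tr] <- f
          t_x[tr] <- x[ii[li]]; t_y[tr] <- y[ii[li]]
        }
      }
    }
    new_locs <- ii[!assigned_loc]
    if (length(new_locs)) {
      ids <- n_tracks + seq_along(new_locs)
      track[new_locs] <- ids
      t_last[ids] <- f; t_x[ids] <- x[new_locs]; t_y[ids] <- y[new_locs]
      n_tracks <- n_tracks + length(new_locs)
    }
  }
  track
}

#' Gap closing and merging of per-frame localizations into on-events
#'
#' Localizations of the same emitter separated by at most
#' `max_off_frames` dark frames and at most `max_distance` nm are merged
#' into one on-event.  Linking is greedy nearest-neighbour in frame
#' order (ThunderSTORM-compatible); merged position is the
#' photon-weighted mean and photons are summed.
#'
#' @param locs a [loc_table()].
#' @param cfg a [merge_config()].
#' @return a [loc_table()] of on-events with columns `frame` (first
#'   frame), `frame_end` (last frame), `n_frames`, and (if present in
#'   the input) the majority `molecule_id`.
#' @export
gap_close_and_merge <- function(locs, cfg) {
  stopifnot(inherits(cfg, "merge_config"))
  if (nrow(locs) == 0) return(locs)
  if (is.unsorted(locs$frame)) {
    warning("input not frame-sorted; sorting internally")
    locs <- locs[order(locs$frame), ]
  }
  fr_end <- if (!is.null(locs$frame_end)) locs$frame_end else locs$frame
  ## linking operates on end-frames so re-merging an already merged
  ## table is a no-op (gaps between distinct on-events exceed the cutoff)
  track <- link_frames(fr_end, locs$x_nm, locs$y_nm, locs$photons,
                       cfg$max_off_frames, cfg$max_distance)
  w <- locs$photons
  if (all(is.na(w))) w <- rep(1, nrow(locs)) else w[is.na(w)] <- mean(w, na.rm = TRUE)
  agg <- function(v, f) vapply(split(v, track), f, numeric(1))
  wx <- agg(w * locs$x_nm, sum) / agg(w, sum)
  wy <- agg(w * locs$y_nm, sum) / agg(w, sum)
  out <- loc_table(
    frame = agg(locs$frame, min),
    x_nm = wx, y_nm = wy,
    photons = if (all(is.na(locs$photons))) NA_real_ else agg(locs$photons, sum),
    uncertainty_nm = agg(locs$uncertainty_nm, function(z) mean(z, na.rm = TRUE)),
    frame_end = agg(fr_end, max),
    n_frames = agg(rep(1, nrow(locs)), sum))
  if (!is.null(locs$molecule_id))
    out$molecule_id <- vapply(split(locs$molecule_id, track), function(z) {
      tt <- table(z); as.integer(names(tt)[which.max(tt)])
    }, integer(1))
  out <- out[order(out$frame, out$x_nm), ]
  rownames(out) <- NULL
  class(out) <- c("loc_table", "data.frame")
  out
}

#' Group merged on-events into molecules and count detections
#'
#' On-events closer than `max_distance` nm whose time separation is at
#' most `cutoff_time` seconds are assigned to one molecule (greedy
#' chaining in frame order).  The per-molecule on-event count N is the
#' input to [fit_geometric_blinking()].
#'
#' @param on_events a merged [loc_table()] (see [gap_close_and_merge()]).
#' @param cfg a [merge_config()] (uses `cutoff_time`, `max_distance`).
#' @param frame_time frame interval in ms.
#' @return data.frame `molecule, n_detections, x_nm, y_nm`.
#' @export
group_molecule_detections <- function(on_events, cfg, frame_time = 1) {
  stopifnot(inherits(cfg, "merge_config"))
  cutoff_frames <- cfg$cutoff_time * 1000 / frame_time
  fr_end <- if (!is.null(on_events$frame_end)) on_events$frame_end
            else on_events$frame
  track <- link_frames(fr_end, on_events$x_nm, on_events$y_nm,
                       on_events$photons, cutoff_frames, cfg$max_distance)
  ns <- vapply(split(seq_along(track), track), length, integer(1))
  xs <- vapply(split(on_events$x_nm, track), mean, numeric(1))
  ys <- vapply(split(on_events$y_nm, track), mean, numeric(1))
  data.frame(molecule = as.integer(names(ns)), n_detections = as.integer(ns),
             x_nm = xs, y_nm = ys, row.names = NULL)
}

#' Render localizations as a Gaussian-blurred image
#'
#' Sum of unit-integral, pixel-integrated 2-D Gaussians centred at the
#' localization positions: total image intensity equals the number of
#' localizations up to edge losses.  Pixel (i, j) covers
#' `[(j-1)*a, j*a) x [(i-1)*a, i*a)` from the field origin (top-left,
#' row = y).
#'
#' @param locs a [loc_table()].
#' @param pixel pixel size a in nm (10 for super-resolution rendering,
#'   55.1 for diffraction-limited).
#' @param sigma rendering Gaussian SD in nm (the localization precision,
#'   29/19 nm; 129 nm for diffraction-limited rendering).
#' @param xlim,ylim field extent in nm; default spans the data padded by
#'   `3 * sigma`.
#' @return numeric matrix (rows = y) with attributes `pixel`, `xlim`,
#'   `ylim`.
#' @export
render <- function(locs, pixel = 10, sigma = 29, xlim = NULL, ylim = NULL) {
  stopifnot(nrow(locs) > 0, pixel > 0, sigma >= 0)
  if (sigma < pixel / 2)
    warning("rendering sigma < pixel/2: image will be aliased")
  if (is.null(xlim)) xlim <- range(locs$x_nm) + c(-4.5, 4.5) * max(sigma, pixel)
  if (is.null(ylim)) ylim <- range(locs$y_nm) + c(-4.5, 4.5) * max(sigma, pixel)
  nx <- max(1L, ceiling((xlim[2] - xlim[1]) / pixel))
  ny <- max(1L, ceiling((ylim[2] - ylim[1]) / pixel))
  img <- matrix(0, nrow = ny, ncol = nx)
  half <- ceiling(4 * sigma / pixel) + 1L
  xe <- xlim[1] + (0:nx) * pixel   # pixel edges
  ye <- ylim[1] + (0:ny) * pixel
  for (i in seq_len(nrow(locs))) {
    cx <- (locs$x_nm[i] - xlim[1]) / pixel
    cy <- (locs$y_nm[i] - ylim[1]) / pixel
    jx <- max(1L, floor(cx) - half + 1L):min(nx, floor(cx) + half + 1L)
    jy <- max(1L, floor(cy) - half + 1L):min(ny, floor(cy) + half + 1L)
    if (sigma == 0) {
      px <- min(nx, max(1L, floor(cx) + 1L))
      py <- min(ny, max(1L, floor(cy) + 1L))
      img[py, px] <- img[py, px] + 1
    } else {
      wx <- diff(pnorm(xe[c(jx, jx[length(jx)] + 1L)], locs$x_nm[i], sigma))
      wy <- diff(pnorm(ye[c(jy, jy[length(jy)] + 1L)], locs$y_nm[i], sigma))
      img[jy, jx] <- img[jy, jx] + outer(wy, wx)
    }
  }
  attr(img, "pixel") <- pixel
  attr(img, "xlim") <- xlim
  attr(img, "ylim") <- ylim
  img
}

#' Sliding-window image reconstruction
#'
#' One rendered frame per `step`; the frame starting at time t uses the
#' localizations in `[t, t + window)`.
#'
#' @param locs a [loc_table()].
#' @param window,step window length and step in seconds.
#' @param frame_time frame interval in ms.
#' @param ... passed to [render()]; `xlim`/`ylim` default to the full
#'   field so all frames share one grid.
#' @return list with `images` (list of matrices) and `t_start_s`.
#' @export
sliding_window_reconstruction <- function(locs, window = 10, step = 1,
                                          frame_time = 1, ...) {
  total_s <- (max(locs$frame) - min(locs$frame) + 1) * frame_time / 1000
  if (window > total_s) stop("window longer than the acquisition")
  dots <- list(...)
  if (is.null(dots$xlim)) dots$xlim <- range(locs$x_nm) + c(-100, 100)
  if (is.null(dots$ylim)) dots$ylim <- range(locs$y_nm) + c(-100, 100)
  f0 <- min(locs$frame)
  starts <- seq(0, total_s - window, by = step)
  images <- lapply(starts, function(t0) {
    fa <- f0 + t0 * 1000 / frame_time
    fb <- fa + window * 1000 / frame_time
    sel <- locs$frame >= fa & locs$frame < fb
    if (!any(sel)) {
      nx <- max(1L, ceiling(diff(dots$xlim) / (dots$pixel %||% 10)))
      ny <- max(1L, ceiling(diff(dots$ylim) / (dots$pixel %||% 10)))
      return(matrix(0, ny, nx))
    }
    do.call(render, c(list(locs[sel, ]), dots))
  })
  list(images = images, t_start_s = starts)
}

#' Per-cluster recruitment time-course
#'
#' For each time window and each circle (candidate loose cluster), the
#' percentage of the localizations inside the FA polygon that fall in
#' that circle: `100 * n(circle) / n(FA)`.
#'
#' @param locs a [loc_table()].
#' @param circles data.frame `x, y, diameter` (nm) of circles inside the
#'   FA polygon.
#' @param fa_polygon list with `x`, `y` vertices (nm).
#' @param window window length in seconds (non-overlapping tiling).
#' @param frame_time frame interval in ms.
#' @return data.frame `window, t_start_s, circle, pct` (`pct` is NA when
#'   the FA contains no localizations in that window).
#' @export
recruitment_timecourse <- function(locs, circles, fa_polygon, window = 10,
                                   frame_time = 1) {
  in_fa <- point_in_poly(locs$x_nm, locs$y_nm, fa_polygon)
  f0 <- min(locs$frame)
  wlen <- window * 1000 / frame_time
  win <- (locs$frame - f0) %/% wlen
  out <- list()
  for (w in sort(unique(win))) {
    sel <- win == w & in_fa
    n_fa <- sum(sel)
    for (ci in seq_len(nrow(circles))) {
      inc <- sum(sel & ((locs$x_nm - circles$x[ci])^2 +
                          (locs$y_nm - circles$y[ci])^2 <
                          (circles$diameter[ci] / 2)^2))
      out[[length(out) + 1]] <- data.frame(
        window = w + 1L, t_start_s = w * window, circle = ci,
        pct = if (n_fa > 0) 100 * inc / n_fa else NA_real_)
    }
  }
  do.call(rbind, out)
}
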