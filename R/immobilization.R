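## Mapping of single-molecule immobilization events onto a
## median-normalized ("thermographic") super-resolution density image.

#' Detect immobilization events in a trajectory
#'
#' A maximal run of at least `min_duration_frames` consecutive positions
#' whose radius of gyration stays below `k_immobile * loc_sigma` is an
#' immobilization event; its circle diameter is
#' `2 * (gyration radius + loc_sigma)` (the printed 104-nm circle at a
#' 21-nm precision anchors the scale: a truly stationary molecule has a
#' gyration radius of about `sqrt(2) * loc_sigma`).
#'
#' @param traj data.frame `frame, x_nm, y_nm` at a fixed frame rate.
#' @param loc_sigma localization precision (nm), > 0.
#' @param min_duration_frames minimum event length in frames.
#' @param k_immobile gyration-radius threshold in units of `loc_sigma`
#'   (default 2, comfortably above the stationary sqrt(2) while
#'   rejecting free diffusion).
#' @param frame_time frame interval (ms), for the reported duration.
#' @return data.frame `start_frame, end_frame, duration_ms, cx, cy,
#'   gyration_radius, circle_diameter` (0 rows if none).
#' @export
detect_immobilization <- function(traj, loc_sigma, min_duration_frames,
                                  k_immobile = 2, frame_time = 4) {
  if (loc_sigma <= 0) stop("loc_sigma must be positive")
  x <- traj$x_nm; y <- traj$y_nm
  n <- length(x)
  thr <- k_immobile * loc_sigma
  events <- list()
  i <- 1L
  while (i + min_duration_frames - 1L <= n) {
    ## greedy expansion: longest run starting at i with Rg <= thr
    j_ok <- NA_integer_
    sx <- 0; sy <- 0; sxx <- 0; syy <- 0
    for (j in i:n) {
      m <- j - i + 1L
      sx <- sx + x[j]; sy <- sy + y[j]
      sxx <- sxx + x[j]^2; syy <- syy + y[j]^2
      rg2 <- (sxx - sx^2 / m + syy - sy^2 / m) / m
      if (sqrt(max(rg2, 0)) <= thr) {
        if (m >= min_duration_frames) j_ok <- j
      } else break
    }
    if (!is.na(j_ok)) {
      idx <- i:j_ok
      m <- length(idx)
      rg <- sqrt(max(mean(x[idx]^2) - mean(x[idx])^2 +
                       mean(y[idx]^2) - mean(y[idx])^2, 0))
      events[[length(events) + 1]] <- data.frame(
        start_frame = traj$frame[i], end_frame = traj$frame[j_ok],
        duration_ms = m * frame_time,
        cx = mean(x[idx]), cy = mean(y[idx]),
        gyration_radius = rg,
        circle_diameter = 2 * (rg + loc_sigma))
      i <- j_ok + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(events))
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_ms = numeric(0), cx = numeric(0),
                      cy = numeric(0), gyration_radius = numeric(0),
                      circle_diameter = numeric(0)))
  do.call(rbind, events)
}

#' Thermographic (median) normalization of a density image
#'
#' Divides the image by the median pixel intensity within the FA mask,
#' so local enrichment is expressed in median-multiples; the display
#' clip range [0, 6] is attached as an attribute.
#'
#' @param image numeric matrix.
#' @param fa_mask logical matrix of the same dimension (nonempty).
#' @return normalized matrix with attribute `clip_range = c(0, 6)`.
#' @export
thermographic_normalize <- function(image, fa_mask) {
  stopifnot(identical(dim(image), dim(fa_mask)), any(fa_mask))
  med <- median(image[fa_mask])
  if (med == 0) stop("zero median intensity within the mask")
  out <- image / med
  attr(out, "clip_range") <- c(0, 6)
  attr(out, "median") <- med
  out
}

#' Normalized intensity at immobilization sites
#'
#' Samples the median-normalized map at each event center (center
#' pixel, or the mean over the event circle when `average_circle`) and
#' reports the fraction of events in above-median territory.
#'
#' @param normalized_map output of [thermographic_normalize()] (with
#'   `pixel`, `xlim`, `ylim` attributes from [render()], or supply
#'   them).
#' @param events data.frame with `cx`, `cy` (nm) and `circle_diameter`.
#' @param pixel,xlim,ylim image geometry overrides (nm).
#' @param average_circle sample the mean over the event circle instead
#'   of the center pixel.
#' @return list: `values` (one per sampled event), `fraction_above_1`,
#'   `n_skipped` (events outside the map).
#' @export
intensity_at_sites <- function(normalized_map, events, pixel = NULL,
                               xlim = NULL, ylim = NULL,
                               average_circle = FALSE) {
  pixel <- pixel %||% attr(normalized_map, "pixel")
  xlim <- xlim %||% attr(normalized_map, "xlim")
  ylim <- ylim %||% attr(normalized_map, "ylim")
  stopifnot(!is.null(pixel), !is.null(xlim), !is.null(ylim))
  ny <- nrow(normalized_map); nx <- ncol(normalized_map)
  vals <- numeric(0); skipped <- 0L
  for (i in seq_len(nrow(events))) {
    jx <- floor((events$cx[i] - xlim[1]) / pixel) + 1L
    jy <- floor((events$cy[i] - ylim[1]) / pixel) + 1L
    if (jx < 1 || jx > nx || jy < 1 || jy > ny) {
      skipped <- skipped + 1L
      next
    }
    if (average_circle && !is.null(events$circle_diameter)) {
      r_px <- events$circle_diameter[i] / 2 / pixel
      jjx <- max(1L, floor(jx - r_px)):min(nx, ceiling(jx + r_px))
      jjy <- max(1L, floor(jy - r_px)):min(ny, ceiling(jy + r_px))
      sub <- expand.grid(y = jjy, x = jjx)
      d <- sqrt((sub$x - jx)^2 + (sub$y - jy)^2)
      sel <- d <= max(r_px, 0.5)
      vals <- c(vals, mean(normalized_map[cbind(sub$y[sel], sub$x[sel])]))
    } else {
      vals <- c(vals, normalized_map[jy, jx])
    }
  }
  if (skipped > 0)
    message(skipped, " event(s) outside the map were skipped")
  list(values = vals, fraction_above_1 = mean(vals > 1),
       n_skipped = skipped)
}
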