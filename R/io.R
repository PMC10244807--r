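#' Localization table constructor
#'
#' A localization table is the universal currency between pipeline stages:
#' one row per detected fluorescent spot (or merged on-event), with the
#' frame index, position in nm, photon count and per-spot localization
#' uncertainty.  Optional columns (`molecule_id`, `event_id`, `frame_end`)
#' carry generator ground truth and merge bookkeeping.
#'
#' @param frame integer frame indices (1-based).
#' @param x_nm,y_nm positions in nm.
#' @param photons detected photons per spot (NA allowed).
#' @param uncertainty_nm per-spot localization SD in nm (NA allowed).
#' @param ... further columns recycled to the common length.
#' @return a `data.frame` of class `loc_table`.
#' @export
loc_table <- function(frame, x_nm, y_nm, photons = NA_real_,
                      uncertainty_nm = NA_real_, ...) {
  df <- data.frame(frame = as.integer(frame), x_nm = x_nm, y_nm = y_nm,
                   photons = photons, uncertainty_nm = uncertainty_nm, ...)
  class(df) <- c("loc_table", "data.frame")
  df
}

#' Read / write localization tables
#'
#' CSV layout: columns `frame, x_nm, y_nm, photons, uncertainty_nm`
#' plus any optional extras (e.g. `molecule_id`).
#'
#' @param path file path.
#' @param locs a `loc_table`.
#' @return `read_localizations` returns a `loc_table`;
#'   `write_localizations` returns `path` invisibly.
#' @export
read_localizations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "x_nm", "y_nm")
  if (!all(need %in% names(df)))
    stop("localization CSV must contain columns: ", paste(need, collapse = ", "))
  if (is.null(df$photons)) df$photons <- NA_real_
  if (is.null(df$uncertainty_nm)) df$uncertainty_nm <- NA_real_
  class(df) <- c("loc_table", "data.frame")
  df
}

#' @rdname read_localizations
#' @export
write_localizations <- function(locs, path) {
  write.csv(as.data.frame(locs), path, row.names = FALSE)
  invisible(path)
}

#' Read / write trajectory tables
#'
#' Trajectory CSV layout: `frame, x_nm, y_nm` at a fixed frame interval.
#'
#' @param path file path.
#' @param traj a data.frame with `frame, x_nm, y_nm`.
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("frame", "x_nm", "y_nm") %in% names(df)))
    stop("trajectory CSV must contain columns frame, x_nm, y_nm")
  df
}

#' @rdname read_trajectory
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj)[, c("frame", "x_nm", "y_nm")], path,
            row.names = FALSE)
  invisible(path)
}

#' Write an image as 32-bit float TIFF
#'
#' @param image numeric matrix.
#' @param path output path.
#' @export
write_image_tiff <- function(image, path) {
  m <- image / max(image, 1e-12)   # writeTIFF expects [0,1]; keep scale in attr
  tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
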