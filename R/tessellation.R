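## Voronoi-density segmentation of focal adhesions and FA-protein
## islands, in the SR-Tesseler style: per-localization densities from the
## Dirichlet (Voronoi) tessellation, thresholding at a multiple of the
## regional mean density, and connected-component grouping of adjacent
## polygons.

#' Segmentation configuration
#'
#' @param density_factor threshold multiple of the regional mean density
#'   (1.45 for both FA and island passes).
#' @param fa_min_diameter minimum FA equivalent diameter in nm (178,
#'   i.e. a minimum area of a 178-nm circle).
#' @param island_min_diameter minimum island equivalent diameter (13 nm).
#' @param island_min_locs minimum localizations per island (6).
#' @param neighbor_rank 0 (own polygon only) or 1 (first-rank averaged
#'   density, the SR-Tesseler convention; default).
#' @export
segmentation_config <- function(density_factor = 1.45,
                                fa_min_diameter = 178,
                                island_min_diameter = 13,
                                island_min_locs = 6,
                                neighbor_rank = 1) {
  stopifnot(density_factor > 1, island_min_locs >= 1,
            neighbor_rank %in% c(0, 1))
  structure(list(density_factor = density_factor,
                 fa_min_diameter = fa_min_diameter,
                 island_min_diameter = island_min_diameter,
                 island_min_locs = island_min_locs,
                 neighbor_rank = neighbor_rank),
            class = "segmentation_config")
}

## deterministic de-duplication jitter: coincident localizations (e.g.
## repeated on-events of one molecule at zero localization error) would
## otherwise be dropped by the tessellation
dedup_jitter <- function(x, y, eps = 0.01) {
  key <- paste(x, y)
  dup <- duplicated(key)
  if (any(dup)) {
    k <- ave(seq_along(key), key, FUN = seq_along) - 1L
    ang <- 2.399963 * seq_along(key)   # golden-angle spread, deterministic
    x <- x + dup * eps * k * cos(ang)
    y <- y + dup * eps * k * sin(ang)
  }
  list(x = x, y = y, n_dup = sum(dup))
}

#' Per-localization Voronoi densities
#'
#' Builds the Voronoi diagram of the localizations clipped to a
#' rectangular ROI and computes the local density of each localization:
#' rank 0 uses `1 / A_i` (own polygon area); rank 1 (default) uses
#' `(1 + n_neighbors) / (A_i + sum of neighbor areas)`, neighbors being
#' polygons sharing a Voronoi edge.
#'
#' @param locs a [loc_table()] or data.frame with `x_nm`, `y_nm`.
#' @param roi rectangle `c(xmin, xmax, ymin, ymax)` (nm); default the
#'   bounding box of the data.
#' @param neighbor_rank 0 or 1.
#' @return object of class `voronoi_density`: `x`, `y`, `area`
#'   (clipped polygon areas, summing to the ROI area), `density`,
#'   `neighbors` (adjacency list), `roi`, `tessellation` (the underlying
#'   `deldir` object).
#' @export
voronoi_densities <- function(locs, roi = NULL, neighbor_rank = 1) {
  x <- locs$x_nm %||% locs$x
  y <- locs$y_nm %||% locs$y
  if (length(x) < 4) stop("need at least 4 localizations in the ROI")
  if (is.null(roi)) roi <- c(range(x), range(y))
  inside <- x >= roi[1] & x <= roi[2] & y >= roi[3] & y <= roi[4]
  x <- x[inside]; y <- y[inside]
  idx_orig <- which(inside)
  dd <- dedup_jitter(x, y)
  x <- dd$x
  y <- dd$y
  dl <- tryCatch(
    deldir::deldir(x, y, rw = roi, suppressMsge = TRUE),
    error = function(e) {
      ## collinear/degenerate input: jitter and retry
      warning("degenerate localization geometry; jittering by 0.01 nm")
      deldir::deldir(x + 0.01 * sin(seq_along(x)),
                     y + 0.01 * cos(seq_along(x)),
                     rw = roi, suppressMsge = TRUE)
    })
  area <- dl$summary$dir.area
  n <- length(x)
  ## adjacency = shared Voronoi edge (dirsgs rows), not shared vertex
  nb <- vector("list", n)
  i1 <- dl$dirsgs$ind1; i2 <- dl$dirsgs$ind2
  for (k in seq_along(i1)) {
    nb[[i1[k]]] <- c(nb[[i1[k]]], i2[k])
    nb[[i2[k]]] <- c(nb[[i2[k]]], i1[k])
  }
  nb <- lapply(nb, unique)
  if (neighbor_rank == 0) {
    dens <- 1 / area
  } else {
    dens <- vapply(seq_len(n), function(i) {
      js <- c(i, nb[[i]])
      length(js) / sum(area[js])
    }, numeric(1))
  }
  structure(list(x = x, y = y, area = area, density = dens,
                 neighbors = nb, roi = roi, index = idx_orig,
                 tessellation = dl),
            class = "voronoi_density")
}

## connected components over the Voronoi adjacency restricted to `keep`
components_over <- function(neighbors, keep) {
  comp <- integer(length(neighbors))
  cur <- 0L
  for (s in which(keep)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] > 0L) next
      comp[v] <- cur
      nxt <- neighbors[[v]]
      nxt <- nxt[keep[nxt] & comp[nxt] == 0L]
      stack <- c(stack, nxt)
    }
  }
  comp
}

#' Detect density-thresholded objects (islands / FAs)
#'
#' Localizations whose Voronoi density is at least `threshold_density`
#' are grouped by shared-Voronoi-edge adjacency; each connected group is
#' an object whose area is the sum of its member polygon areas and whose
#' equivalent diameter is `d = 2 * sqrt(A / pi)`.  Objects below
#' `min_diameter` or `min_locs` are discarded.
#'
#' @param vd a [voronoi_densities()] result.
#' @param threshold_density absolute density threshold (localizations
#'   per nm^2), typically `factor * mean density of the region`.
#' @param min_diameter,min_locs object acceptance thresholds.
#' @param subset optional integer vector: restrict detection (members
#'   and connectivity) to these localization indices.
#' @return data.frame of class `island_records`: `object, area,
#'   diameter, n_locs, cx, cy` with a list-column `members`.
#' @export
detect_objects <- function(vd, threshold_density, min_diameter = 13,
                           min_locs = 6, subset = NULL) {
  stopifnot(inherits(vd, "voronoi_density"))
  keep <- vd$density >= threshold_density
  if (!is.null(subset)) {
    mask <- rep(FALSE, length(keep)); mask[subset] <- TRUE
    keep <- keep & mask
  }
  comp <- components_over(vd$neighbors, keep)
  recs <- list()
  for (cc in seq_len(max(comp, 0L))) {
    mem <- which(comp == cc)
    if (length(mem) < min_locs) next
    ## membership and counts use the (smoothed) density threshold; the
    ## object area counts the member polygons that are dense in their
    ## own right (1/A_i >= threshold).  Edge polygons straddle the
    ## object boundary and extend far into the sparse surroundings, so
    ## their full extent would overstate the object footprint.
    core <- 1 / vd$area[mem] >= threshold_density
    A <- sum(vd$area[mem][core])
    if (A <= 0) next
    d <- 2 * sqrt(A / pi)
    if (d < min_diameter) next
    recs[[length(recs) + 1]] <- data.frame(
      area = A, diameter = d, n_locs = length(mem),
      cx = mean(vd$x[mem]), cy = mean(vd$y[mem]))
    attr(recs[[length(recs)]], "members") <- mem
  }
  if (!length(recs)) {
    out <- data.frame(object = integer(0), area = numeric(0),
                      diameter = numeric(0), n_locs = integer(0),
                      cx = numeric(0), cy = numeric(0))
    out$members <- list()
    class(out) <- c("island_records", "data.frame")
    return(out)
  }
  mems <- lapply(recs, attr, "members")
  out <- do.call(rbind, recs)
  out <- cbind(object = seq_len(nrow(out)), out)
  out$members <- mems
  rownames(out) <- NULL
  class(out) <- c("island_records", "data.frame")
  out
}

#' Outline polygon of a detected object
#'
#' Union of the member Voronoi tiles (via polygon clipping); returns the
#' largest ring.
#'
#' @param vd a [voronoi_densities()] result.
#' @param members integer indices of member localizations.
#' @return list with `x`, `y` vertices.
#' @export
object_polygon <- function(vd, members) {
  tl <- deldir::tile.list(vd$tessellation)
  polys <- lapply(members, function(i) list(x = tl[[i]]$x, y = tl[[i]]$y))
  u <- polys[[1]]
  if (length(polys) > 1) {
    acc <- list(u)
    for (i in 2:length(polys)) {
      acc <- polyclip::polyclip(acc, polys[[i]], op = "union")
    }
    u <- acc[[which.max(vapply(acc, function(p)
      abs(pracma::polyarea(p$x, p$y)), numeric(1)))]]
  }
  u
}

#' Two-pass segmentation: focal adhesions, then islands inside each FA
#'
#' Pass 1 detects FA objects against the whole-field dataset average
#' density (`N / ROI area`) with the FA minimum area (178-nm circle).
#' Pass 2 detects islands among each FA's member localizations against
#' the mean per-localization density of that FA, with the island
#' thresholds (>= 13 nm, >= 6 localizations).  Islands are nested in
#' their parent FA by construction.
#'
#' @param locs a [loc_table()].
#' @param cfg a [segmentation_config()].
#' @param roi rectangle `c(xmin, xmax, ymin, ymax)`; default data bbox.
#' @return list of class `segmentation_result`: `fa` (island_records of
#'   FA objects), `islands` (island_records with `fa_id` column),
#'   `voronoi` (the tessellation), `mean_density`, `cfg`.
#' @export
segment_fa_and_islands <- function(locs, cfg = segmentation_config(),
                                   roi = NULL) {
  vd <- voronoi_densities(locs, roi = roi, neighbor_rank = cfg$neighbor_rank)
  ## FA pass: threshold relative to the dataset average density
  ## (N / ROI area); the FA is enriched several-fold over the whole
  ## field, so its polygons clear this comfortably
  roi_area <- (vd$roi[2] - vd$roi[1]) * (vd$roi[4] - vd$roi[3])
  rho0 <- length(vd$x) / roi_area
  fa <- detect_objects(vd, cfg$density_factor * rho0,
                       min_diameter = cfg$fa_min_diameter, min_locs = 1)
  islands <- NULL
  if (nrow(fa) == 0) {
    message("no FA object found at the given density factor")
  } else {
    isl <- list()
    for (i in seq_len(nrow(fa))) {
      mem <- fa$members[[i]]
      ## island pass: threshold relative to the mean per-localization
      ## density of the FA's members — the convention under which the
      ## Monte-Carlo size calibration tracks the identity line at
      ## factor 1.45 for zero localization error
      rho_fa <- mean(vd$density[mem])
      ii <- detect_objects(vd, cfg$density_factor * rho_fa,
                           min_diameter = cfg$island_min_diameter,
                           min_locs = cfg$island_min_locs, subset = mem)
      if (nrow(ii)) {
        ii$fa_id <- fa$object[i]
        isl[[length(isl) + 1]] <- ii
      }
    }
    if (length(isl)) {
      islands <- do.call(rbind, isl)
      islands$object <- seq_len(nrow(islands))
    }
  }
  structure(list(fa = fa, islands = islands, voronoi = vd,
                 mean_density = rho0, cfg = cfg),
            class = "segmentation_result")
}

#' Serialize a segmentation result
#'
#' Writes per-island CSV (area, diameter, n_locs) and a JSON summary
#' with FA/island outline polygons as vertex lists (nm).
#'
#' @param seg a `segmentation_result`.
#' @param csv_path,json_path output paths (either may be NULL).
#' @export
write_segmentation <- function(seg, csv_path = NULL, json_path = NULL) {
  tab <- if (!is.null(seg$islands))
    seg$islands[, c("object", "fa_id", "area", "diameter", "n_locs")]
  else data.frame()
  if (!is.null(csv_path)) write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    polys_fa <- lapply(seq_len(nrow(seg$fa)), function(i)
      object_polygon(seg$voronoi, seg$fa$members[[i]]))
    polys_isl <- if (!is.null(seg$islands))
      lapply(seq_len(nrow(seg$islands)), function(i)
        object_polygon(seg$voronoi, seg$islands$members[[i]]))
    else list()
    jsonlite::write_json(
      list(mean_density = seg$mean_density,
           fa = lapply(seq_along(polys_fa), function(i)
             list(area = seg$fa$area[i], diameter = seg$fa$diameter[i],
                  n_locs = seg$fa$n_locs[i], polygon = polys_fa[[i]])),
           islands = lapply(seq_along(polys_isl), function(i)
             list(fa_id = seg$islands$fa_id[i],
                  area = seg$islands$area[i],
                  diameter = seg$islands$diameter[i],
                  n_locs = seg$islands$n_locs[i],
                  polygon = polys_isl[[i]]))),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(seg)
}

#' Binarize an image
#'
#' Global minimum-cross-entropy thresholding (Li's iterative method) or
#' Sauvola's local thresholding (window radius in pixels, parameters `k`
#' and dynamic range `r`).
#'
#' @param image numeric matrix.
#' @param method "min_cross_entropy" or "sauvola".
#' @param radius Sauvola window radius (pixels), default 64.
#' @param k,r Sauvola parameters, defaults 0.5 and 128.
#' @return logical matrix mask.
#' @export
binarize_image <- function(image, method = c("min_cross_entropy", "sauvola"),
                           radius = 64, k = 0.5, r = 128) {
  method <- match.arg(method)
  if (max(image) == min(image)) {
    warning("constant image: returning all-FALSE mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  if (method == "min_cross_entropy") {
    v <- as.vector(image)
    v <- v - min(v)
    t_old <- mean(v)
    for (it in 1:200) {   # Li & Tam iterative minimum cross entropy
      lo <- v[v <= t_old]; hi <- v[v > t_old]
      m0 <- mean(lo); m1 <- mean(hi)
      if (!is.finite(m0) || m0 <= 0) m0 <- .Machine$double.eps
      if (!is.finite(m1) || m1 <= 0) m1 <- .Machine$double.eps
      t_new <- (m1 - m0) / (log(m1) - log(m0))
      if (!is.finite(t_new)) t_new <- (m0 + m1) / 2
      if (abs(t_new - t_old) < 1e-8) break
      t_old <- t_new
    }
    return(matrix(as.vector(image) - min(image) > t_old,
                  nrow(image), ncol(image)))
  }
  ## Sauvola: T = m * (1 + k * (s / r - 1)) over a (2*radius+1) box
  mu <- box_mean(image, radius)
  mu2 <- box_mean(image^2, radius)
  s <- sqrt(pmax(mu2 - mu^2, 0))
  image > mu * (1 + k * (s / r - 1))
}

## box mean via integral image, edge-clipped window
box_mean <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  ii <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  r1 <- pmax(seq_len(nr) - radius, 1); r2 <- pmin(seq_len(nr) + radius, nr)
  c1 <- pmax(seq_len(nc) - radius, 1); c2 <- pmin(seq_len(nc) + radius, nc)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    a <- ii[r2 + 1, c2[j] + 1] - ii[r1, c2[j] + 1] -
         ii[r2 + 1, c1[j]] + ii[r1, c1[j]]
    out[, j] <- a / ((r2 - r1 + 1) * (c2[j] - c1[j] + 1))
  }
  out
}
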