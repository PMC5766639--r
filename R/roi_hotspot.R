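# Hot-spot ROI extraction: the round region with the most extreme mean
# value on a parametric map within a tumor mask. Discs are 2D in-plane —
# thick slices with a gap make 3D spheres anisotropic and slices
# effectively independent.

# Integer in-plane offsets of a disc of the given radius (mm), honoring
# the in-plane voxel size. Always includes the center voxel.
disc_offsets <- function(radius_mm, voxel_size) {
  vx <- voxel_size[1]; vy <- voxel_size[2]
  rx <- floor(radius_mm / vx); ry <- floor(radius_mm / vy)
  dx <- rep(seq(-rx, rx), times = 2 * ry + 1)
  dy <- rep(seq(-ry, ry), each = 2 * rx + 1)
  keep <- (dx * vx)^2 + (dy * vy)^2 <= radius_mm^2 + 1e-9
  cbind(dx = dx[keep], dy = dy[keep])
}

#' Extract the hot-spot ROI on a parametric map
#'
#' Evaluates the mean map value within an in-plane circular disc at every
#' candidate center whose disc lies fully within the mask (and within map
#' validity), and returns the center maximizing (`mode = "max"`) or
#' minimizing (`mode = "min"`) that mean. Ties are broken by the first
#' center in scan order (slices, then rows, then columns). If no disc of
#' the requested radius fits inside the mask, the radius is shrunk by one
#' in-plane voxel step at a time (logged via `message()`), down to a
#' single voxel.
#'
#' @param map a [parametric_map].
#' @param mask optional 3D logical tumor mask (default: the map's own
#'   validity mask); intersected with map validity.
#' @param radius_mm disc radius, mm (default 5).
#' @param mode `"max"` (perfusion-type maps) or `"min"` (diffusion-type).
#' @return An object of class `hotspot_roi` with fields `center` (0-based
#'   voxel coordinates, x/y/z), `radius_mm` (effective radius used),
#'   `mode`, `mean_value`, `n_voxels`.
#' @export
extract_hotspot <- function(map, mask = NULL, radius_mm = 5,
                            mode = c("max", "min")) {
  mode <- match.arg(mode)
  if (radius_mm <= 0) stop("radius must be positive")
  d <- dim(map$values)
  if (is.null(mask)) mask <- map$mask
  mask <- array(as.logical(mask), dim(as.array(mask)))
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  if (!identical(dim(mask), d))
    stop("map and mask must be on the same grid")
  elig <- mask & map$mask
  if (!any(elig)) stop("mask is empty (no valid voxels)")
  step <- min(map$voxel_size[1:2])
  r <- radius_mm
  repeat {
    off <- disc_offsets(r, map$voxel_size)
    res <- hotspot_scan(map$values, elig, off, mode)
    if (!is.null(res)) break
    r_new <- r - step
    if (r_new <= 0) {
      # degenerate single-voxel disc always fits on a non-empty mask
      off <- cbind(dx = 0L, dy = 0L)
      res <- hotspot_scan(map$values, elig, off, mode)
      r <- 0
      break
    }
    message(sprintf(
      "no disc of radius %.3g mm fits inside the mask; shrinking to %.3g mm",
      r, r_new))
    r <- r_new
  }
  structure(list(center = res$center - 1L,  # 0-based, x/y/z
                 radius_mm = r, mode = mode,
                 mean_value = res$mean, n_voxels = nrow(off)),
            class = "hotspot_roi")
}

# Scan all candidate centers; returns NULL when no disc fits.
hotspot_scan <- function(values, elig, off, mode) {
  d <- dim(values)
  best_mean <- NA_real_
  best_center <- NULL
  sgn <- if (mode == "max") 1 else -1
  for (z in seq_len(d[3])) {
    sl <- elig[, , z]
    if (!any(sl)) next
    vz <- values[, , z]
    for (y in seq_len(d[2])) {
      for (x in seq_len(d[1])) {
        xs <- x + off[, "dx"]; ys <- y + off[, "dy"]
        if (any(xs < 1L) || any(xs > d[1]) || any(ys < 1L) || any(ys > d[2]))
          next
        ii <- cbind(xs, ys)
        if (!all(sl[ii])) next
        m <- mean(vz[ii])
        if (is.null(best_center) || sgn * m > sgn * best_mean) {
          best_mean <- m
          best_center <- c(x, y, z)
        }
      }
    }
  }
  if (is.null(best_center)) return(NULL)
  list(center = best_center, mean = best_mean)
}

#' @export
print.hotspot_roi <- function(x, ...) {
  cat(sprintf(
    "hot-spot ROI (%s): center (%d, %d, %d) [0-based], r = %.3g mm, mean = %.5g over %d voxels\n",
    x$mode, x$center[1], x$center[2], x$center[3], x$radius_mm,
    x$mean_value, x$n_voxels))
  invisible(x)
}

#' Propagate a hot-spot ROI onto another parametric map
#'
#' Recomputes the disc voxels from the ROI's center and radius and returns
#' the mean of the target map over those voxels. Grids must have identical
#' dimensions (co-registration is assumed upstream). Disc voxels that are
#' invalid on the target map are dropped with a warning.
#'
#' @param roi a `hotspot_roi` from [extract_hotspot()].
#' @param target_map a [parametric_map] on the same grid.
#' @return Mean value of the target map over the ROI disc.
#' @export
propagate_roi <- function(roi, target_map) {
  d <- dim(target_map$values)
  ctr <- roi$center + 1L
  if (any(ctr < 1L) || any(ctr > d))
    stop("ROI center lies outside the target grid; dimensions must match")
  off <- if (roi$radius_mm > 0)
    disc_offsets(roi$radius_mm, target_map$voxel_size)
  else cbind(dx = 0L, dy = 0L)
  xs <- ctr[1] + off[, "dx"]; ys <- ctr[2] + off[, "dy"]
  if (any(xs < 1L) || any(xs > d[1]) || any(ys < 1L) || any(ys > d[2]))
    stop("ROI disc falls outside the target grid; dimensions must match")
  ii <- cbind(xs, ys, ctr[3])
  valid <- target_map$mask[ii]
  if (!any(valid)) stop("no valid target voxels under the ROI")
  if (!all(valid))
    warning(sprintf("%d ROI voxel(s) invalid on target map were dropped",
                    sum(!valid)))
  mean(target_map$values[ii][valid])
}
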