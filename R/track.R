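## ---- internal sampling machinery -------------------------------------------

.sample_bilinear <- function(M, rows, cols) {
  h <- nrow(M); w <- ncol(M)
  r0 <- clamp(floor(rows), 1, h - 1L)
  c0 <- clamp(floor(cols), 1, w - 1L)
  fr <- clamp(rows - r0, 0, 1)
  fc <- clamp(cols - c0, 0, 1)
  v <- as.vector(M)
  i00 <- (c0 - 1) * h + r0
  v00 <- v[i00]; v10 <- v[i00 + 1L]
  v01 <- v[i00 + h]; v11 <- v[i00 + h + 1L]
  out <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
         v01 * (1 - fr) * fc + v11 * fr * fc
  dim(out) <- dim(rows)
  out
}

## Precompute radial sampling coordinates: R rays x K radii.
.ray_grid <- function(center, angles, radii) {
  rows <- center[1] + outer(sin(angles), radii)
  cols <- center[2] + outer(cos(angles), radii)
  list(rows = rows, cols = cols, radii = radii, angles = angles)
}

## All threshold crossings of profile p (sampled at radii) at level thr,
## linearly interpolated to sub-pixel radius. dir +1 = upward (below -> above).
.profile_crossings <- function(p, radii, thr) {
  s <- p >= thr
  d <- diff(s)
  idx <- which(d != 0L)
  if (!length(idx)) return(list(r = numeric(0), dir = integer(0)))
  frac <- (thr - p[idx]) / (p[idx + 1L] - p[idx])
  list(r = radii[idx] + frac * (radii[idx + 1L] - radii[idx]),
       dir = as.integer(d[idx]))
}

## ---- initial border detection ----------------------------------------------

#' Detect the tablet's initial border in frame 0
#'
#' Segments the first frame into dyed medium versus tablet foreground with an
#' Otsu threshold on a blueness index (`B - (R+G)/2`, normalized), finds the
#' single connected tablet region, and measures the sub-pixel border radius
#' along uniformly spaced rays from the foreground centroid.
#'
#' The returned geometry also carries the reference quantities every later
#' tracking step reuses: the fixed blueness threshold, the median medium
#' color, and the median distance-to-medium ("mediumness") of the tablet
#' interior.
#'
#' @param stack an [image_stack].
#' @param rays number of rays (>= 8; default 360).
#' @return object of class `tablet_geometry` with fields `center` (row, col),
#'   `ray_angles`, `initial_radius` (mm per ray), `initial_radius_px`,
#'   `pixel_size`, `dim`, `blue_threshold`, `medium_color`,
#'   `core_mediumness`.
#' @export
detect_initial_border <- function(stack, rays = 360L) {
  stopifnot(inherits(stack, "image_stack"))
  rays <- as.integer(rays)
  if (rays < 8L) stop("detect_initial_border: need at least 8 rays")
  f0 <- stack$frames[[1]]
  b0 <- blueness_index(f0)
  thr <- otsu_threshold(b0)
  fg <- b0 < thr
  if (!any(fg)) stop("tablet not found")
  lab <- label_components(fg)
  keep <- which(lab$sizes >= 25L)
  if (!length(keep)) stop("tablet not found")
  ord <- keep[order(lab$sizes[keep], decreasing = TRUE)]
  main <- ord[1]
  if (length(ord) > 1L && lab$sizes[ord[2]] >= 0.5 * lab$sizes[main])
    stop("ambiguous foreground")
  mask <- lab$labels == main
  h <- nrow(mask); w <- ncol(mask)
  touches <- c(any(mask[1, ]), any(mask[h, ]), any(mask[, 1]), any(mask[, w]))
  if (all(touches)) stop("tablet not found")
  idx <- which(mask, arr.ind = TRUE)
  center <- c(mean(idx[, 1]), mean(idx[, 2]))
  bg <- !fg
  medium_color <- vapply(1:3, function(ch) stats::median(f0[, , ch][bg]),
                         numeric(1))
  med0 <- mediumness_index(f0, medium_color)
  core_mediumness <- stats::median(med0[mask])
  angles <- seq(0, 2 * pi, length.out = rays + 1L)[-(rays + 1L)]
  rmax <- min(center[1] - 1, h - center[1], center[2] - 1, w - center[2])
  radii <- seq(0, rmax, by = 0.5)
  grid <- .ray_grid(center, angles, radii)
  prof <- .sample_bilinear(b0, grid$rows, grid$cols)
  r0_px <- rep(NA_real_, rays)
  for (j in seq_len(rays)) {
    cr <- .profile_crossings(prof[j, ], radii, thr)
    up <- cr$r[cr$dir > 0L]
    if (length(up)) r0_px[j] <- max(up)
  }
  if (anyNA(r0_px)) stop("tablet not found")
  structure(list(center = center, ray_angles = angles,
                 initial_radius = r0_px * stack$pixel_size,
                 initial_radius_px = r0_px,
                 pixel_size = stack$pixel_size, dim = c(h, w),
                 blue_threshold = thr, medium_color = medium_color,
                 core_mediumness = core_mediumness),
            class = "tablet_geometry")
}

#' @export
print.tablet_geometry <- function(x, ...) {
  cat(sprintf("tablet_geometry: center (%.2f, %.2f) px, %d rays, radius %.3f +/- %.3f mm\n",
              x$center[1], x$center[2], length(x$ray_angles),
              mean(x$initial_radius), stats::sd(x$initial_radius)))
  invisible(x)
}

## ---- boundary traces -------------------------------------------------------

.check_geometry <- function(stack, geometry) {
  if (!identical(dim(stack$frames[[1]])[1:2], as.integer(geometry$dim)) &&
      !all(dim(stack$frames[[1]])[1:2] == geometry$dim))
    stop("geometry mismatch")
}

.new_trace <- function(kind, stack, per_ray_px, occluded, geometry) {
  n_f <- nrow(per_ray_px); n_r <- ncol(per_ray_px)
  ## per-ray zero baseline: distances are defined relative to the frame-0
  ## border measured by the same estimator, so frame 0 is exactly 0 and any
  ## constant sub-pixel threshold bias cancels
  base <- per_ray_px[1, ]
  base[is.na(base)] <- 0
  rel <- sweep(per_ray_px, 2, base)
  rel[!is.na(rel) & rel < 0] <- 0
  if (kind == "wetting")
    rel <- pmin(rel, matrix(geometry$initial_radius_px, n_f, n_r, byrow = TRUE))
  mm <- rel * geometry$pixel_size
  usable <- !occluded & !is.na(mm)
  n_used <- rowSums(usable)
  distance <- vapply(seq_len(n_f), function(i) {
    if (n_used[i] < n_r / 2) return(NA_real_)  # front not measurable
    stats::median(mm[i, usable[i, ]])
  }, numeric(1))
  structure(list(kind = kind, times = stack$timestamps,
                 per_ray_distance = mm, occluded = occluded,
                 distance = distance, n_rays_used = n_used,
                 replicate_id = stack$replicate_id, medium = stack$medium,
                 pixel_size = geometry$pixel_size),
            class = "boundary_trace")
}

#' @export
print.boundary_trace <- function(x, ...) {
  cat(sprintf("boundary_trace (%s): %d frames, %d rays, distance %.3f..%.3f mm, replicate '%s' in '%s'\n",
              x$kind, length(x$times), ncol(x$per_ray_distance),
              min(x$distance, na.rm = TRUE), max(x$distance, na.rm = TRUE),
              x$replicate_id, x$medium))
  invisible(x)
}

#' @export
as.data.frame.boundary_trace <- function(x, ...) {
  df <- data.frame(time_min = x$times, distance_mm = x$distance,
                   n_rays_used = x$n_rays_used, kind = x$kind,
                   replicate_id = x$replicate_id, medium = x$medium,
                   stringsAsFactors = FALSE)
  ## erosion is measured as an edge distance; the doubled diameter
  ## convention is emitted alongside for comparability
  if (x$kind == "erosion") df$distance_diameter_mm <- 2 * x$distance
  df
}

#' Track the dye wetting front through a stack
#'
#' For each frame and ray the wetting (liquid penetration) distance is the
#' initial border radius minus the radius of the innermost stained/unstained
#' transition of the blueness profile inside the border. Rays whose interior
#' profile has multiple threshold crossings (bubble artifacts) are flagged
#' occluded; rays stained all the way to the center are flagged saturated
#' (NA) and a frame whose majority of rays is unusable reports NA distance.
#'
#' @param stack an [image_stack].
#' @param geometry geometry from [detect_initial_border()] on the same stack.
#' @param dye_threshold `"auto"` (Otsu threshold computed on frame 0 and held
#'   fixed) or a numeric threshold on the normalized blueness index.
#' @return a `boundary_trace` with `kind = "wetting"`.
#' @export
track_wetting_front <- function(stack, geometry, dye_threshold = "auto") {
  .check_geometry(stack, geometry)
  thr <- if (identical(dye_threshold, "auto")) geometry$blue_threshold
         else as.numeric(dye_threshold)
  n_f <- length(stack$frames)
  angles <- geometry$ray_angles
  n_r <- length(angles)
  r0 <- geometry$initial_radius_px
  radii <- seq(0, max(r0), by = 0.5)
  grid <- .ray_grid(geometry$center, angles, radii)
  per_ray <- matrix(NA_real_, n_f, n_r)
  occl <- matrix(FALSE, n_f, n_r)
  for (i in seq_len(n_f)) {
    B <- blueness_index(stack$frames[[i]])
    prof <- .sample_bilinear(B, grid$rows, grid$cols)
    for (j in seq_len(n_r)) {
      win <- radii <= r0[j]
      p <- prof[j, win]; rr <- radii[win]
      cr <- .profile_crossings(p, rr, thr)
      up <- cr$r[cr$dir > 0L]
      if (length(up) == 0L) {
        ## uniform profile: all dye (front passed center) or no dye at all
        per_ray[i, j] <- if (all(p >= thr)) NA_real_ else 0
        next
      }
      ## several upward transitions into dye inside the border: bubble or
      ## split front on this ray
      if (length(up) > 1L) occl[i, j] <- TRUE
      per_ray[i, j] <- r0[j] - min(up)
    }
  }
  .new_trace("wetting", stack, per_ray, occl, geometry)
}

#' Track the outer gel boundary through a stack
#'
#' The gel halo is searched only outward of the initial border: the gel
#' thickness on a ray is the outermost radius at which the distance-to-medium
#' profile drops to the medium level, minus the initial radius, floored at 0.
#'
#' @inheritParams track_wetting_front
#' @return a `boundary_trace` with `kind = "gel"`.
#' @export
track_gel_boundary <- function(stack, geometry) {
  .check_geometry(stack, geometry)
  n_f <- length(stack$frames)
  angles <- geometry$ray_angles
  n_r <- length(angles)
  r0 <- geometry$initial_radius_px
  h <- geometry$dim[1]; w <- geometry$dim[2]
  rmax <- min(geometry$center[1] - 1, h - geometry$center[1],
              geometry$center[2] - 1, w - geometry$center[2])
  radii <- seq(0, rmax, by = 0.5)
  grid <- .ray_grid(geometry$center, angles, radii)
  thr <- 0.25 * geometry$core_mediumness
  per_ray <- matrix(NA_real_, n_f, n_r)
  occl <- matrix(FALSE, n_f, n_r)
  for (i in seq_len(n_f)) {
    M <- mediumness_index(stack$frames[[i]], geometry$medium_color)
    prof <- .sample_bilinear(M, grid$rows, grid$cols)
    for (j in seq_len(n_r)) {
      win <- radii >= r0[j] - 0.75
      p <- prof[j, win]; rr <- radii[win]
      cr <- .profile_crossings(p, rr, thr)
      down <- cr$r[cr$dir < 0L]
      if (length(down) == 0L) {
        ## gel beyond the sampled field -> saturated; no gel at all -> 0
        per_ray[i, j] <- if (all(p >= thr)) NA_real_ else 0
        next
      }
      if (length(down) > 1L) occl[i, j] <- TRUE
      per_ray[i, j] <- max(max(down) - r0[j], 0)
    }
  }
  .new_trace("gel", stack, per_ray, occl, geometry)
}

#' Track the erosion boundary through a stack
#'
#' Erosion is searched only inward of the initial border: the erosion
#' distance on a ray is the initial radius minus the outermost radius at
#' which tablet matter (distance-to-medium above a fixed fraction of the
#' frame-0 interior level) ends. Rays whose interior profile crosses the
#' matter threshold more than once, or whose crossing overlaps a detected
#' bright bubble blob, are flagged occluded and excluded from the aggregate.
#'
#' @inheritParams track_wetting_front
#' @return a `boundary_trace` with `kind = "erosion"`.
#' @export
track_erosion_boundary <- function(stack, geometry) {
  .check_geometry(stack, geometry)
  n_f <- length(stack$frames)
  angles <- geometry$ray_angles
  n_r <- length(angles)
  r0 <- geometry$initial_radius_px
  radii <- seq(0, max(r0) + 1.5, by = 0.5)
  grid <- .ray_grid(geometry$center, angles, radii)
  thr <- 0.15 * geometry$core_mediumness
  ctr <- round(geometry$center)
  per_ray <- matrix(NA_real_, n_f, n_r)
  occl <- matrix(FALSE, n_f, n_r)
  for (i in seq_len(n_f)) {
    f <- stack$frames[[i]]
    M <- mediumness_index(f, geometry$medium_color)
    prof <- .sample_bilinear(M, grid$rows, grid$cols)
    ## bright circular blobs (gas bubbles): bright components not containing
    ## the tablet center
    lum <- luminance_index(f)
    bright <- lum > 0.85
    bub_mask <- NULL
    if (any(bright)) {
      lab <- label_components(bright)
      core_lab <- lab$labels[ctr[1], ctr[2]]
      bm <- lab$labels > 0L & lab$labels != core_lab
      if (any(bm)) bub_mask <- bm
    }
    bprof <- if (!is.null(bub_mask))
      .sample_bilinear(bub_mask * 1, grid$rows, grid$cols) else NULL
    for (j in seq_len(n_r)) {
      win <- radii <= r0[j] + 1.5
      p <- prof[j, win]; rr <- radii[win]
      cr <- .profile_crossings(p, rr, thr)
      down <- cr$r[cr$dir < 0L]
      if (length(down) == 0L) {
        ## all matter -> boundary at/past the border (no erosion); none -> gone
        per_ray[i, j] <- if (all(p >= thr)) 0 else NA_real_
        next
      }
      ## matter ends more than once along the ray: bubble in the eroded gap
      if (length(down) > 1L) occl[i, j] <- TRUE
      rc <- max(down)
      if (!is.null(bprof) &&
          any(bprof[j, win][abs(rr - rc) <= 3] > 0.25)) occl[i, j] <- TRUE
      per_ray[i, j] <- max(r0[j] - rc, 0)
    }
  }
  .new_trace("erosion", stack, per_ray, occl, geometry)
}

#' Write a boundary trace as CSV
#'
#' Columns: `time_min, distance_mm, n_rays_used, kind, replicate_id, medium`.
#'
#' @param trace a `boundary_trace`.
#' @param path output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
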