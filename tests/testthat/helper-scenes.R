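## Small rendered scenes reused across test files (computed once per run).

.scene_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, spec_fun) {
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- simulate_immersion_stack(spec_fun())
  .scene_cache[[key]]
}

## canonical small wetting scene: 2 px/frame front at 0.05 mm/px, 1 min/frame
wetting_sim <- function() cached_sim("wetting", function()
  scene_spec(width = 192, height = 192, radius_px = 60, pixel_size = 0.05,
             n_frames = 11, wetting_velocity = 0.1, seed = 101))

gel_sim <- function() cached_sim("gel", function()
  scene_spec(width = 192, height = 192, radius_px = 55, pixel_size = 0.05,
             n_frames = 11, gel_velocity = 0.05, seed = 102))

## slope of the aggregated trace of a simulated stack
tracked_slope <- function(sim, kind, rays = 180) {
  g <- detect_initial_border(sim$stack, rays = rays)
  tr <- switch(kind,
               wetting = track_wetting_front(sim$stack, g),
               gel = track_gel_boundary(sim$stack, g),
               erosion = track_erosion_boundary(sim$stack, g))
  estimate_rate(suppressWarnings(trace_to_series(tr)))$slope
}

## rotate an H x W x 3 frame by 90 degrees
rotate_frame_90 <- function(f) {
  out <- array(0, dim = c(dim(f)[2], dim(f)[1], 3L))
  for (ch in 1:3) out[, , ch] <- t(f[, , ch])[, dim(f)[1]:1]
  out
}

## uniform medium-colored stack (no tablet anywhere)
blank_stack <- function(n = 2L, side = 64L) {
  f <- array(0, dim = c(side, side, 3L))
  f[, , 1] <- 0.15; f[, , 2] <- 0.25; f[, , 3] <- 0.95
  image_stack(rep(list(f), n), seq_len(n) - 1, 0.05)
}

## frame with white disks drawn on medium background
disk_frame <- function(side, centers, radii) {
  f <- array(0, dim = c(side, side, 3L))
  f[, , 1] <- 0.15; f[, , 2] <- 0.25; f[, , 3] <- 0.95
  for (i in seq_along(radii)) {
    rr <- sqrt(outer((seq_len(side) - centers[[i]][1])^2,
                     (seq_len(side) - centers[[i]][2])^2, `+`))
    m <- pmin(pmax(radii[i] - rr + 0.5, 0), 1)
    f[, , 1] <- f[, , 1] * (1 - m) + 0.95 * m
    f[, , 2] <- f[, , 2] * (1 - m) + 0.95 * m
    f[, , 3] <- f[, , 3] * (1 - m) + 0.92 * m
  }
  f
}

## published table subsets used in several tests
published_hcl_wetting_p407 <- function() {
  r <- reference_rates()
  w <- r[r$medium == "HCl_pH1.2" & r$kind == "wetting" &
         r$formulation_id != "IBU", ]
  w[match(c("IP", "IP5E", "IP10E", "IP20E", "IP25E", "IP30E"),
          w$formulation_id), "mean_rate"]
}

published_ps_k1_p407 <- function() {
  k <- reference_kinetics()
  p <- k[k$model_id == "PS" & k$formulation_id != "IBU", ]
  p[match(c("IP", "IP5E", "IP10E", "IP20E", "IP25E", "IP30E"),
          p$formulation_id), "k1"]
}
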