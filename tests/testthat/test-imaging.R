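test_that("initial border detection recovers radius and center of a synthetic disk", {
  ## centered disk, radius 100 px at 0.05 mm/px -> 5.0 mm on every ray
  s <- scene_spec(width = 256, height = 256, radius_px = 100,
                  pixel_size = 0.05, n_frames = 2, seed = 1)
  sim <- simulate_immersion_stack(s)
  g <- detect_initial_border(sim$stack, rays = 90)
  expect_s3_class(g, "tablet_geometry")
  expect_equal(length(g$initial_radius), 90L)
  expect_true(all(abs(g$initial_radius - 5.0) < 0.05))  # within 1 px
  expect_true(all(abs(g$center - s$center) < 1))

  ## off-center disk: recovered center within 1 px of generator's center
  s2 <- scene_spec(width = 256, height = 256,
                   center = c(128.5 + 20, 128.5 - 15), radius_px = 60,
                   pixel_size = 0.05, n_frames = 2, seed = 2)
  g2 <- detect_initial_border(simulate_immersion_stack(s2)$stack, rays = 90)
  expect_true(all(abs(g2$center - s2$center) < 1))
})

test_that("border detection errors: blank frame, ambiguous foreground, ray floor", {
  expect_error(detect_initial_border(blank_stack()), "tablet not found")
  two <- disk_frame(128, list(c(40, 40), c(90, 90)), c(20, 18))
  st <- image_stack(list(two, two), c(0, 1), 0.05)
  expect_error(detect_initial_border(st), "ambiguous foreground")
  expect_error(detect_initial_border(wetting_sim()$stack, rays = 4),
               "at least 8 rays")
})

test_that("static stacks give identically-zero distance for all three boundaries", {
  s <- scene_spec(width = 160, height = 160, radius_px = 50,
                  pixel_size = 0.05, n_frames = 5, seed = 3)
  sim <- simulate_immersion_stack(s)
  expect_true(all(vapply(sim$stack$frames,
                         function(f) identical(f, sim$stack$frames[[1]]),
                         logical(1))))
  g <- detect_initial_border(sim$stack, rays = 120)
  for (fn in list(track_wetting_front, track_gel_boundary,
                  track_erosion_boundary)) {
    tr <- fn(sim$stack, g)
    expect_equal(tr$distance, rep(0, 5), tolerance = 1e-12)
  }
})

test_that("wetting front at 2 px/frame yields distance ~ 0.1 t mm and matching slope", {
  sim <- wetting_sim()
  g <- detect_initial_border(sim$stack, rays = 180)
  tr <- track_wetting_front(sim$stack, g)
  expect_identical(tr$kind, "wetting")
  expect_equal(tr$distance[1], 0)
  expect_true(all(abs(tr$distance - 0.1 * tr$times) < 0.05))
  sl <- estimate_rate(trace_to_series(tr))$slope
  expect_lt(abs(sl / 0.1 - 1), 0.02)
  ## distance never exceeds the initial radius
  expect_true(all(tr$per_ray_distance <= max(g$initial_radius) + 1e-9,
                  na.rm = TRUE))
})

test_that("fully-stained tablet saturates to NA frames and rate uses the rest", {
  ## front crosses the whole radius in ~3 min; later frames must be NA
  s <- scene_spec(width = 160, height = 160, radius_px = 50,
                  pixel_size = 0.05, n_frames = 9,
                  wetting_velocity = 0.8, seed = 104)
  sim <- simulate_immersion_stack(s)
  g <- detect_initial_border(sim$stack, rays = 120)
  tr <- track_wetting_front(sim$stack, g)
  expect_true(anyNA(tr$distance))
  sl <- estimate_rate(suppressWarnings(trace_to_series(tr)))$slope
  expect_lt(abs(sl / 0.8 - 1), 0.02)
})

test_that("gel halo growth is recovered and a saturating halo plateaus", {
  sim <- gel_sim()
  g <- detect_initial_border(sim$stack, rays = 180)
  tr <- track_gel_boundary(sim$stack, g)
  expect_identical(tr$kind, "gel")
  sl <- estimate_rate(trace_to_series(tr))$slope
  expect_lt(abs(sl / 0.05 - 1), 0.02)

  ## halo frozen after minute 10: append static copies of the last frame
  fr <- c(sim$stack$frames, rep(sim$stack$frames[11], 4))
  st2 <- image_stack(fr, 0:14, 0.05)
  g2 <- detect_initial_border(st2, rays = 120)
  tr2 <- track_gel_boundary(st2, g2)
  late <- tr2$distance[11:15]
  expect_lt(max(late) - min(late), 1e-9)
  expect_equal(tr2$distance[15], tr2$distance[11])
})

test_that("no halo present means zero gel distance", {
  sim <- wetting_sim()   # wetting-only scene has no gel
  g <- detect_initial_border(sim$stack, rays = 120)
  tr <- track_gel_boundary(sim$stack, g)
  expect_true(all(abs(tr$distance) < 1e-9))
})

test_that("rough erosion is recovered within 10% and bubbles occlude rays", {
  s <- scene_spec(width = 256, height = 256, radius_px = 80,
                  pixel_size = 0.05, n_frames = 31,
                  erosion_velocity = 0.02, roughness_sd = 1, seed = 105)
  sim <- simulate_immersion_stack(s)
  g <- detect_initial_border(sim$stack, rays = 180)
  tr <- track_erosion_boundary(sim$stack, g)
  sl <- estimate_rate(trace_to_series(tr))$slope
  expect_lt(abs(sl / 0.02 - 1), 0.10)

  ## bubbles: occluded rays exist, are excluded, and the slope survives
  s2 <- scene_spec(width = 256, height = 256, radius_px = 80,
                   pixel_size = 0.05, n_frames = 11,
                   erosion_velocity = 0.05, bubble_count = 12, seed = 106)
  sim2 <- simulate_immersion_stack(s2)
  g2 <- detect_initial_border(sim2$stack, rays = 180)
  tr2 <- track_erosion_boundary(sim2$stack, g2)
  expect_gt(sum(tr2$occluded), 0)
  expect_true(all(tr2$n_rays_used == rowSums(!tr2$occluded &
                                             !is.na(tr2$per_ray_distance))))
  sl2 <- estimate_rate(trace_to_series(tr2))$slope
  expect_lt(abs(sl2 / 0.05 - 1), 0.10)
})

test_that("tracking distances are invariant to a 90-degree scene rotation", {
  sim <- wetting_sim()
  st2 <- image_stack(lapply(sim$stack$frames, rotate_frame_90),
                     sim$stack$timestamps, sim$stack$pixel_size)
  tr1 <- track_wetting_front(sim$stack,
                             detect_initial_border(sim$stack, rays = 120))
  tr2 <- track_wetting_front(st2, detect_initial_border(st2, rays = 120))
  ## aggregated distance differs by less than one pixel-equivalent
  expect_true(all(abs(tr1$distance - tr2$distance) < sim$stack$pixel_size))
})

test_that("doubling pixel_size doubles all reported mm distances exactly", {
  sim <- wetting_sim()
  st2 <- image_stack(sim$stack$frames, sim$stack$timestamps,
                     2 * sim$stack$pixel_size)
  tr1 <- track_wetting_front(sim$stack,
                             detect_initial_border(sim$stack, rays = 120))
  tr2 <- track_wetting_front(st2, detect_initial_border(st2, rays = 120))
  expect_equal(tr2$distance, 2 * tr1$distance, tolerance = 1e-12)
})

test_that("monotone fronts give non-decreasing median-smoothed distance", {
  for (tr in list(
    track_wetting_front(wetting_sim()$stack,
                        detect_initial_border(wetting_sim()$stack, rays = 120)),
    track_gel_boundary(gel_sim()$stack,
                       detect_initial_border(gel_sim()$stack, rays = 120)))) {
    sm <- stats::runmed(tr$distance, 3)
    expect_true(all(diff(sm) > -1e-9))
  }
})

test_that("geometry mismatch and trace serialization", {
  sim <- wetting_sim()
  g <- detect_initial_border(sim$stack, rays = 120)
  other <- blank_stack(side = 100)
  expect_error(track_wetting_front(other, g), "geometry mismatch")
  expect_error(track_gel_boundary(other, g), "geometry mismatch")
  expect_error(track_erosion_boundary(other, g), "geometry mismatch")

  tr <- track_wetting_front(sim$stack, g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  df <- read.csv(path)
  expect_named(df, c("time_min", "distance_mm", "n_rays_used", "kind",
                     "replicate_id", "medium"))
  expect_equal(nrow(df), length(tr$times))
  expect_equal(df$distance_mm, tr$distance, tolerance = 1e-9)
})
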