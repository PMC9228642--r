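## Rendering palette for synthetic immersion scenes. The appearance model:
## saturated blue medium, white tablet, dye-penetrated annulus blended toward
## the medium color, gel halo as a 50%-alpha whitish blend over the medium,
## gas bubbles as bright discs. All edges are anti-aliased over ~1 px so
## sub-pixel crossings are recoverable by linear interpolation.
.scene_colors <- list(
  medium = c(0.15, 0.25, 0.95),
  tablet = c(0.95, 0.95, 0.92),
  gel    = c(0.90, 0.90, 0.88),
  bubble = c(0.97, 0.99, 1.00)
)
.dye_alpha <- 0.65      # fraction of medium color blended into stained matter
.gel_alpha <- 0.5       # translucency of the gel halo over the medium

#' Specification of a synthetic tablet-immersion scene
#'
#' States the world a rendered stack lives in: geometry, calibration, front
#' kinematics and noise. Defaults follow the canonical acquisition (31 frames
#' at 1 frame/min) and a 12.7 mm diameter tablet at 0.05 mm/px in a 512x512
#' frame.
#'
#' @param width,height frame size in pixels.
#' @param center `(row, col)` tablet center in pixels; default is the frame
#'   center.
#' @param radius_px initial tablet radius in pixels.
#' @param pixel_size millimetres per pixel.
#' @param frame_interval minutes between frames.
#' @param n_frames number of frames (>= 2).
#' @param wetting_velocity,gel_velocity,erosion_velocity front speeds in
#'   mm/min (all >= 0). The wetting front moves inward, the gel halo outward,
#'   the outer boundary inward.
#' @param roughness_sd per-ray Gaussian roughness of the outer boundary, px.
#' @param bubble_count bright gas-bubble discs rendered near the outer
#'   boundary per frame.
#' @param bubble_radius_range bubble radius range in px.
#' @param noise_sd Gaussian pixel noise SD as a fraction of dynamic range.
#' @param seed integer seed fixing all randomness.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width = 512L, height = 512L, center = NULL,
                       radius_px = 127, pixel_size = 0.05,
                       frame_interval = 1, n_frames = 31L,
                       wetting_velocity = 0, gel_velocity = 0,
                       erosion_velocity = 0, roughness_sd = 0,
                       bubble_count = 0L, bubble_radius_range = c(3, 8),
                       noise_sd = 0, seed = 1L) {
  if (is.null(center)) center <- c((height + 1) / 2, (width + 1) / 2)
  if (any(c(wetting_velocity, gel_velocity, erosion_velocity) < 0))
    stop("scene_spec: velocities must be >= 0")
  if (n_frames < 2L) stop("scene_spec: need at least 2 frames")
  t_end <- (n_frames - 1) * frame_interval
  if (radius_px - erosion_velocity * t_end / pixel_size <= 0)
    stop("tablet consumed before last frame")
  structure(list(width = as.integer(width), height = as.integer(height),
                 center = center, radius_px = radius_px,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 wetting_velocity = wetting_velocity,
                 gel_velocity = gel_velocity,
                 erosion_velocity = erosion_velocity,
                 roughness_sd = roughness_sd,
                 bubble_count = as.integer(bubble_count),
                 bubble_radius_range = bubble_radius_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

## soft inside-mask of radius R over a precomputed radius map: 1 inside,
## linear 1-px anti-aliasing ramp across the boundary
.soft_in <- function(Rb, rmap) clamp(Rb - rmap + 0.5, 0, 1)

#' Render a synthetic immersion stack with ground truth
#'
#' Deterministically (per seed) renders a disk whose dye front advances
#' inward at constant speed, whose gel halo grows outward, and whose outer
#' boundary recedes with optional per-ray roughness and bright bubble
#' artifacts, then adds Gaussian pixel noise. A ground-truth sidecar with the
#' per-frame true radii is returned alongside the stack.
#'
#' The wetting front clamps at radius 0 once the tablet is fully stained
#' (fast-wetting formulations reach this within the 30 min window); total
#' erosion beyond the initial radius is rejected at [scene_spec()] time.
#'
#' @param spec a [scene_spec].
#' @param replicate_id,medium labels stored in the stack.
#' @return list with elements `stack` ([image_stack]) and `truth` (list of
#'   per-frame wetting/gel/erosion radii in px and mm, roughness control
#'   points and bubble tables).
#' @export
simulate_immersion_stack <- function(spec, replicate_id = "sim1",
                                     medium = "water") {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    cy <- spec$center[1]; cx <- spec$center[2]
    rmap <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`))
    amap <- atan2(outer(seq_len(h) - cy, rep(1, w)),
                  outer(rep(1, h), seq_len(w) - cx))
    times <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
    px <- spec$pixel_size
    R0 <- spec$radius_px
    rw <- pmax(R0 - spec$wetting_velocity * times / px, 0)
    rg <- R0 + spec$gel_velocity * times / px
    re <- R0 - spec$erosion_velocity * times / px
    cols <- .scene_colors
    n_ctrl <- 64L
    ctrl_ang <- seq(-pi, pi, length.out = n_ctrl + 1L)[-(n_ctrl + 1L)]
    frames <- vector("list", spec$n_frames)
    rough_ctrl <- matrix(0, spec$n_frames, n_ctrl)
    bubbles <- vector("list", spec$n_frames)
    for (k in seq_len(spec$n_frames)) {
      ## per-frame roughness: smooth periodic perturbation of outer boundary
      if (spec$roughness_sd > 0 && k > 1L) {
        pert <- stats::rnorm(n_ctrl, 0, spec$roughness_sd)
        rough_ctrl[k, ] <- pert
        dmap <- stats::approx(c(ctrl_ang, pi),
                              c(pert, pert[1]),
                              xout = as.vector(amap), rule = 2)$y
        re_map <- re[k] + matrix(dmap, h, w)
      } else re_map <- matrix(re[k], h, w)
      mt <- .soft_in(re_map, rmap)
      mg <- .gel_alpha * .soft_in(rg[k], rmap) * (1 - .soft_in(R0, rmap))
      fd <- 1 - .soft_in(rw[k], rmap)   # stained fraction of tablet matter
      ## bubbles near the current outer boundary
      bub <- NULL
      if (spec$bubble_count > 0L && k > 1L) {
        br <- stats::runif(spec$bubble_count, spec$bubble_radius_range[1],
                           spec$bubble_radius_range[2])
        bang <- stats::runif(spec$bubble_count, -pi, pi)
        ## bubbles sit just outside the receding matter edge, from slightly
        ## overlapping it to detached in the eroded gap
        brad <- re[k] + br * stats::runif(spec$bubble_count, 0.8, 1.6)
        bub <- data.frame(row = cy + brad * sin(bang),
                          col = cx + brad * cos(bang), radius = br)
      }
      bubbles[[k]] <- bub
      frame <- array(0, dim = c(h, w, 3L))
      for (ch in 1:3) {
        img <- cols$medium[ch] * (1 - mg) + cols$gel[ch] * mg
        tab <- cols$tablet[ch] * (1 - .dye_alpha * fd) +
               cols$medium[ch] * .dye_alpha * fd
        img <- img * (1 - mt) + tab * mt
        frame[, , ch] <- img
      }
      if (!is.null(bub)) {
        for (j in seq_len(nrow(bub))) {
          rb <- sqrt(outer((seq_len(h) - bub$row[j])^2,
                           (seq_len(w) - bub$col[j])^2, `+`))
          mb <- .soft_in(bub$radius[j], rb)
          for (ch in 1:3)
            frame[, , ch] <- frame[, , ch] * (1 - mb) + cols$bubble[ch] * mb
        }
      }
      if (spec$noise_sd > 0)
        frame <- clamp(frame + stats::rnorm(length(frame), 0, spec$noise_sd), 0, 1)
      frames[[k]] <- frame
    }
    stack <- image_stack(frames, times, px, replicate_id = replicate_id,
                         medium = medium)
    truth <- list(times_min = times,
                  wetting_radius_px = rw, gel_radius_px = rg,
                  erosion_radius_px = re,
                  wetting_distance_mm = (R0 - rw) * px,
                  gel_distance_mm = (rg - R0) * px,
                  erosion_distance_mm = (R0 - re) * px,
                  center = spec$center, radius_px = R0,
                  roughness_ctrl = rough_ctrl, bubbles = bubbles,
                  spec = spec)
    list(stack = stack, truth = truth)
  })
}

#' Simulate a cumulative dissolution profile from a kinetic model
#'
#' Evaluates the model at the given times and adds seeded Gaussian noise,
#' clipping to `[0, 100]`%.
#'
#' @param spec a [kinetic_model_spec] or a model id (`"KP_F0"`, `"PS"`).
#' @param parameters named parameter vector for the model.
#' @param times hours, strictly increasing.
#' @param noise_sd Gaussian noise SD in percentage points (>= 0).
#' @param seed seed for the noise; required when `noise_sd > 0`.
#' @param formulation_id label carried into the profile.
#' @return a [dissolution_profile].
#' @export
simulate_dissolution <- function(spec, parameters, times, noise_sd = 0,
                                 seed = 1L, formulation_id = "sim") {
  if (is.character(spec)) spec <- kinetic_model_spec(spec)
  if (any(diff(times) <= 0)) stop("bad time axis")
  if (noise_sd < 0) stop("simulate_dissolution: noise_sd must be >= 0")
  f <- eval_model(spec, parameters, times)
  ## noiseless output is exactly the model evaluation (kinetic parameter sets
  ## whose curve dips marginally below 0 at early times stay unclipped);
  ## noisy values are clipped to the physical range
  if (noise_sd > 0)
    f <- clamp(with_local_seed(seed, f + stats::rnorm(length(f), 0, noise_sd)),
               0, 100)
  dissolution_profile(times, f, formulation_id = formulation_id)
}

#' Generate a complete synthetic study fixture
#'
#' Renders immersion stacks, dissolution profiles and a disintegration-time
#' table for a catalogue of formulations, emulating the study layout (seven
#' formulations, two media, five imaging replicates each). Front velocities
#' default to the packaged published mean rates (replicate velocities drawn
#' from the published mean +/- SD, truncated at 0); kinetic parameters
#' default to the packaged published Peppas-Sahlin rows. Everything is
#' seed-deterministic.
#'
#' The tablet disk is auto-sized per stack so that the full 31-frame
#' recession and gel growth fit inside the frame (the fastest published
#' erosion rate recedes further in 30 min than a 12.7 mm tablet's radius).
#'
#' @param config list (or path to a JSON file) with optional keys:
#'   `out_dir` (required), `formulations`, `media`, `n_replicates`,
#'   `radius_px`, `pixel_size`, `frame_interval`, `n_frames`,
#'   `roughness_sd`, `bubble_count`, `noise_sd`, `times_h`, `noise_pct`,
#'   `seed`, `ascii`. Unknown keys are rejected by name.
#' @return invisibly, a list describing the written bundle (paths and the
#'   per-stack ground-truth velocities).
#' @export
make_study_fixture <- function(config) {
  config <- validate_run_config(config, required = "out_dir")
  rates <- reference_rates()
  kin <- reference_kinetics()
  catalogue <- unique(rates$formulation_id)
  forms <- config$formulations %||% catalogue
  bad <- setdiff(forms, catalogue)
  if (length(bad)) stop("not in fixture catalogue: ", paste(bad, collapse = ", "))
  media <- config$media %||% c("water", "HCl_pH1.2")
  n_rep <- config$n_replicates %||% 5L
  px <- config$pixel_size %||% 0.05
  r_def <- config$radius_px %||% 127
  dt_frame <- config$frame_interval %||% 1
  n_frames <- config$n_frames %||% 31L
  seed <- config$seed %||% 1L
  times_h <- config$times_h %||% c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 24)
  out_dir <- config$out_dir
  dir.create(file.path(out_dir, "stacks"), recursive = TRUE, showWarnings = FALSE)
  t_end <- (n_frames - 1) * dt_frame
  truth <- list()
  si <- 0L
  for (fm in forms) for (med in media) {
    get_rate <- function(kd) {
      r <- rates[rates$formulation_id == fm & rates$medium == med &
                 rates$kind == kd, ]
      c(mean = r$mean_rate[1], sd = r$sd_rate[1])
    }
    vw <- get_rate("wetting"); vg <- get_rate("gel"); ve <- get_rate("erosion")
    for (rep_i in seq_len(n_rep)) {
      si <- si + 1L
      draw <- function(v, s) {
        if (is.na(v["mean"])) return(0)  # ND front: nothing to render
        max(with_local_seed(s, stats::rnorm(1, v["mean"], v["sd"])), 0)
      }
      sseed <- seed + 1000L * si
      v_w <- draw(vw, sseed + 1L); v_g <- draw(vg, sseed + 2L)
      v_e <- draw(ve, sseed + 3L)
      ## auto-size the disk so erosion never consumes it and gel fits
      need_r <- v_e * t_end / px + 40
      r0 <- max(r_def, ceiling(need_r))
      half <- ceiling(r0 + max(v_g * t_end / px, 0) + 10)
      side <- 2L * as.integer(half) + 1L
      spec <- scene_spec(width = side, height = side, radius_px = r0,
                         pixel_size = px, frame_interval = dt_frame,
                         n_frames = n_frames,
                         wetting_velocity = v_w, gel_velocity = v_g,
                         erosion_velocity = v_e,
                         roughness_sd = config$roughness_sd %||% 0,
                         bubble_count = config$bubble_count %||% 0L,
                         noise_sd = config$noise_sd %||% 0,
                         seed = sseed)
      rep_id <- paste0(fm, "__rep", rep_i)
      sim <- simulate_immersion_stack(spec, replicate_id = rep_id, medium = med)
      sdir <- file.path(out_dir, "stacks",
                        paste0(fm, "_", gsub("[^A-Za-z0-9._-]", "-", med),
                               "_rep", rep_i))
      write_image_stack(sim$stack, sdir, ascii = isTRUE(config$ascii))
      truth[[length(truth) + 1L]] <-
        list(dir = sdir, formulation_id = fm, medium = med,
             replicate = rep_i, wetting_velocity = v_w,
             gel_velocity = v_g, erosion_velocity = v_e,
             radius_px = r0, pixel_size = px)
    }
  }
  ## dissolution profiles from the published Peppas-Sahlin rows
  dis <- do.call(rbind, lapply(forms, function(fm) {
    row <- kin[kin$formulation_id == fm & kin$model_id == "PS", ]
    prof <- simulate_dissolution("PS",
      c(k1 = row$k1, k2 = row$k2, m = row$m), times_h,
      noise_sd = config$noise_pct %||% 0, seed = seed + match(fm, catalogue),
      formulation_id = fm)
    data.frame(formulation_id = fm, time_h = prof$times,
               pct_dissolved = prof$released, stringsAsFactors = FALSE)
  }))
  utils::write.csv(dis, file.path(out_dir, "dissolution.csv"), row.names = FALSE)
  dtab <- reference_disintegration()
  dtab <- dtab[dtab$formulation_id %in% forms & dtab$medium %in% media, ]
  utils::write.csv(dtab, file.path(out_dir, "disintegration.csv"),
                   row.names = FALSE)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(out_dir = out_dir, stacks = truth,
                 dissolution_csv = file.path(out_dir, "dissolution.csv"),
                 disintegration_csv = file.path(out_dir, "disintegration.csv")))
}
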