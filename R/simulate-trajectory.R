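# Ground-truth crawl simulator. The movement model is deliberately simple:
# a heading random walk with four behavioral modes (forward/reverse runs,
# pauses, lateral head casts) switched by a first-order Markov chain, inside
# a rectangular arena with reflective walls. It exists to give the tracker
# and the statistics known kinematics to recover, not to model larval
# biomechanics.

#' Simulate a ground-truthed larval crawl trajectory
#'
#' Generates per-frame true centroids, headings, behavioral mode labels and
#' instantaneous locomotion speeds for one recording. Optionally injects
#' "teleports": instantaneous centroid jumps that mimic the experimenter
#' manually re-centering the animal when it leaves the field of view. Every
#' injected jump is larger than `teleport_min_displacement` body lengths
#' (> 0.5 by validation), so each one trips the half-body-length displacement
#' exclusion rule downstream.
#'
#' The true speed series records locomotion only: during a pause it is 0 and
#' during a teleport it stays at the current mode's speed, because the jump
#' is repositioning, not crawling. Away from arena walls and teleports,
#' consecutive true centroids are exactly `speed / frame_rate / pixel_scale`
#' pixels apart.
#'
#' @param config A [kinematics_config()].
#'
#' @return A `larva_track`: a tibble with one row per frame and columns
#'   `frame`, `x_px`, `y_px`, `heading`, `mode`, `speed_um_s`, `is_teleport`
#'   (`is_teleport` marks the *first* frame of a jump pair), plus attributes
#'   `body_length_px`, `body_area_px`, `frame_rate`, `pixel_scale`,
#'   `teleport_frames` and `config`. Deterministic for a fixed seed.
#' @export
#' @examples
#' trk <- simulate_trajectory(kinematics_config(n_frames = 50, seed = 7))
#' head(trk)
simulate_trajectory <- function(config) {
  cfg <- validate_kinematics_config(config)
  n <- cfg$n_frames
  dt <- 1 / cfg$frame_rate
  step_scale <- dt / cfg$pixel_scale # um/s -> px per frame
  bl <- cfg$body_length_px
  margin <- bl / 2 + 2
  w <- cfg$arena_size[1]
  h <- cfg$arena_size[2]
  if (w - 2 * margin <= bl || h - 2 * margin <= bl) {
    abort("Invalid configuration: `arena_size` too small for the body length.")
  }

  set.seed(cfg$seed)
  modes <- draw_modes(cfg, n)
  teleport_at <- if (cfg$n_teleports > 0) {
    sort(sample(seq_len(n - 1L), cfg$n_teleports))
  } else {
    integer()
  }

  x <- y <- heading <- speed <- numeric(n)
  # start away from walls so short fixtures never reflect
  x[1] <- runif(1, w / 3, 2 * w / 3)
  y[1] <- runif(1, h / 3, 2 * h / 3)
  heading[1] <- runif(1, 0, 2 * pi)
  cast_side <- 1
  min_jump <- cfg$teleport_min_displacement * bl

  for (i in seq_len(n)) {
    side_used <- cast_side
    v <- mode_velocity(modes[i], heading[i], cfg, cast_side)
    if (modes[i] == "head_cast") cast_side <- -cast_side
    speed[i] <- sqrt(sum(v^2))
    if (i == n) break
    heading[i + 1] <- heading[i]
    if (i %in% teleport_at) {
      # instantaneous repositioning: uniform target far enough from here
      repeat {
        tx <- runif(1, margin, w - margin)
        ty <- runif(1, margin, h - margin)
        if (sqrt((tx - x[i])^2 + (ty - y[i])^2) > min_jump) break
      }
      x[i + 1] <- tx
      y[i + 1] <- ty
    } else if (speed[i] == 0) {
      x[i + 1] <- x[i]
      y[i + 1] <- y[i]
    } else {
      stp <- reflect_step(x[i], y[i], v[1] * step_scale, v[2] * step_scale,
                          margin, w - margin, margin, h - margin)
      x[i + 1] <- stp[1]
      y[i + 1] <- stp[2]
      if (stp[4] > 0) {
        heading[i + 1] <- heading_from_direction(modes[i], stp[3], side_used)
      }
    }
    heading[i + 1] <- heading[i + 1] + rnorm(1, 0, cfg$heading_noise)
  }

  trk <- tibble::tibble(
    frame = seq_len(n), x_px = x, y_px = y, heading = heading,
    mode = modes, speed_um_s = speed,
    is_teleport = seq_len(n) %in% teleport_at
  )
  structure(trk,
    class = c("larva_track", class(trk)),
    body_length_px = bl,
    body_area_px = pi * (bl / 2) * (bl / 6),
    frame_rate = cfg$frame_rate,
    pixel_scale = cfg$pixel_scale,
    teleport_frames = teleport_at,
    config = cfg
  )
}

draw_modes <- function(cfg, n) {
  if (!is.null(cfg$mode_sequence)) {
    if (length(cfg$mode_sequence) == 1L) {
      return(rep(cfg$mode_sequence, n))
    }
    return(cfg$mode_sequence)
  }
  modes <- character(n)
  modes[1] <- "run_forward"
  for (i in seq_len(n - 1L)) {
    modes[i + 1] <- sample(crawl_modes, 1, prob = cfg$transition[modes[i], ])
  }
  modes
}

# velocity in um/s for a mode; head casts sweep the centroid laterally
mode_velocity <- function(mode, heading, cfg, cast_side) {
  switch(mode,
    run_forward = cfg$run_speed * c(cos(heading), sin(heading)),
    run_reverse = -cfg$run_speed * c(cos(heading), sin(heading)),
    pause = c(0, 0),
    head_cast = cast_side * cfg$head_cast_speed_frac * cfg$run_speed *
      c(-sin(heading), cos(heading))
  )
}

# invert mode_velocity: given the direction of motion after a wall
# reflection, recover the heading that would have produced it
heading_from_direction <- function(mode, phi, cast_side) {
  switch(mode,
    run_forward = phi,
    run_reverse = phi + pi,
    head_cast = phi - cast_side * pi / 2,
    phi
  )
}

# take one step with specular reflection off the walls; returns
# c(x, y, new_heading, n_reflections). Reflection preserves the distance
# traveled along the folded path.
reflect_step <- function(x, y, dx, dy, xmin, xmax, ymin, ymax) {
  nx <- x + dx
  ny <- y + dy
  refl <- 0L
  for (k in 1:4) { # a small step can fold at most a couple of times
    moved <- FALSE
    if (nx < xmin) { nx <- 2 * xmin - nx; dx <- -dx; refl <- refl + 1L; moved <- TRUE }
    if (nx > xmax) { nx <- 2 * xmax - nx; dx <- -dx; refl <- refl + 1L; moved <- TRUE }
    if (ny < ymin) { ny <- 2 * ymin - ny; dy <- -dy; refl <- refl + 1L; moved <- TRUE }
    if (ny > ymax) { ny <- 2 * ymax - ny; dy <- -dy; refl <- refl + 1L; moved <- TRUE }
    if (!moved) break
  }
  c(nx, ny, atan2(dy, dx), refl)
}

#' @export
print.larva_track <- function(x, ...) {
  cat(sprintf(
    "<larva_track> %d frames @ %g Hz, %g um/px, body %g px, %d teleport(s)\n",
    nrow(x), attr(x, "frame_rate"), attr(x, "pixel_scale"),
    attr(x, "body_length_px"), length(attr(x, "teleport_frames"))
  ))
  NextMethod()
}

#' Write / read a ground-truth track as CSV with a JSON sidecar
#'
#' The CSV holds the per-frame series (`frame`, `x_px`, `y_px`, `heading`,
#' `mode`, `speed_um_s`, `is_teleport`); the sidecar
#' (`<path>.json`) records frame rate, pixel scale, body size and the
#' generating configuration, so a track round-trips losslessly.
#'
#' @param track A `larva_track`.
#' @param path CSV file path.
#' @return `write_track` returns `path` invisibly; `read_track` returns a
#'   `larva_track`.
#' @export
write_track <- function(track, path) {
  write.csv(as.data.frame(track), path, row.names = FALSE)
  meta <- list(
    body_length_px = attr(track, "body_length_px"),
    body_area_px = attr(track, "body_area_px"),
    frame_rate = attr(track, "frame_rate"),
    pixel_scale = attr(track, "pixel_scale"),
    teleport_frames = attr(track, "teleport_frames"),
    config = unclass(attr(track, "config"))
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(df,
    class = c("larva_track", class(df)),
    body_length_px = meta$body_length_px,
    body_area_px = meta$body_area_px,
    frame_rate = meta$frame_rate,
    pixel_scale = meta$pixel_scale,
    teleport_frames = as.integer(meta$teleport_frames),
    config = meta$config
  )
}
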