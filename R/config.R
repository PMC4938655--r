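# Configuration constructors for the synthetic-data generators. Each is a
# validated list; invalid fields abort with the offending field named, so a
# bad simulation never runs silently.

#' Crawl kinematics configuration
#'
#' Parameters of the synthetic larva's movement model. Behavioral modes are
#' `run_forward`, `run_reverse`, `pause` and `head_cast`; switching follows a
#' first-order Markov chain unless an explicit `mode_sequence` is supplied.
#' Defaults emulate a newly hatched first-instar larva recorded at low
#' magnification: 4 Hz, 800 frames, a body about 0.6 mm long spanning ~20
#' pixels, and a run speed near the permissive-temperature control mean.
#'
#' @param frame_rate Acquisition rate, Hz. Must be positive.
#' @param n_frames Number of frames (>= 2).
#' @param pixel_scale Spatial calibration, micrometres per pixel.
#' @param arena_size Integer vector `c(width, height)` in pixels.
#' @param mode_sequence Optional character vector of modes, either length 1
#'   (constant mode) or length `n_frames`. Overrides the Markov chain.
#' @param transition One of the built-in transition presets (`"explore"`,
#'   a run-dominated ethogram, or `"uniform"`), or a 4x4 row-stochastic
#'   matrix with dimnames over the four modes.
#' @param run_speed Crawl speed during runs, micrometres per second.
#' @param head_cast_speed_frac Lateral centroid speed during head casts, as a
#'   fraction of `run_speed`. The centroid moves perpendicular to the heading,
#'   alternating side each frame (zigzag).
#' @param heading_noise Standard deviation of the per-frame heading random
#'   walk, radians.
#' @param body_length_px Body length in pixels; sets the teleport-exclusion
#'   scale and the default rendered ellipse.
#' @param n_teleports Number of instantaneous repositioning jumps to inject,
#'   mimicking manual re-centering of the animal during recording.
#' @param teleport_min_displacement Minimum jump size in body lengths; must
#'   exceed 0.5 so that every injected jump trips the half-body-length
#'   exclusion rule by construction.
#' @param seed Integer seed; all randomness in [simulate_trajectory()] flows
#'   from it.
#'
#' @return An object of class `kinematics_config`.
#' @seealso [simulate_trajectory()]
#' @export
#' @examples
#' cfg <- kinematics_config(n_frames = 100, mode_sequence = "run_forward")
kinematics_config <- function(frame_rate = 4,
                              n_frames = 800,
                              pixel_scale = 30,
                              arena_size = c(160L, 120L),
                              mode_sequence = NULL,
                              transition = "explore",
                              run_speed = 100,
                              head_cast_speed_frac = 0.4,
                              heading_noise = 0.15,
                              body_length_px = 20,
                              n_teleports = 0,
                              teleport_min_displacement = 1,
                              seed = 1L) {
  cfg <- list(
    frame_rate = frame_rate, n_frames = as.integer(n_frames),
    pixel_scale = pixel_scale, arena_size = as.integer(arena_size),
    mode_sequence = mode_sequence,
    transition = resolve_transition(transition),
    run_speed = run_speed, head_cast_speed_frac = head_cast_speed_frac,
    heading_noise = heading_noise, body_length_px = body_length_px,
    n_teleports = as.integer(n_teleports),
    teleport_min_displacement = teleport_min_displacement,
    seed = as.integer(seed)
  )
  class(cfg) <- "kinematics_config"
  validate_kinematics_config(cfg)
}

crawl_modes <- c("run_forward", "run_reverse", "pause", "head_cast")

resolve_transition <- function(transition) {
  if (is.matrix(transition)) {
    if (!identical(dim(transition), c(4L, 4L))) {
      abort("`transition` matrix must be 4x4 over the four crawl modes.")
    }
    if (is.null(dimnames(transition))) {
      dimnames(transition) <- list(crawl_modes, crawl_modes)
    }
    return(transition[crawl_modes, crawl_modes])
  }
  preset <- match.arg(transition, c("explore", "uniform"))
  if (preset == "uniform") {
    m <- matrix(0.25, 4, 4, dimnames = list(crawl_modes, crawl_modes))
    return(m)
  }
  # run-dominated ethogram: long forward runs interrupted by brief pauses,
  # head casts and occasional short reversals
  m <- rbind(
    run_forward = c(0.94, 0.01, 0.03, 0.02),
    run_reverse = c(0.30, 0.65, 0.03, 0.02),
    pause       = c(0.25, 0.02, 0.70, 0.03),
    head_cast   = c(0.25, 0.02, 0.03, 0.70)
  )
  colnames(m) <- crawl_modes
  m
}

validate_kinematics_config <- function(cfg) {
  check_field(cfg$frame_rate > 0, "frame_rate", "must be > 0")
  check_field(cfg$n_frames >= 2, "n_frames", "must be >= 2")
  check_field(cfg$pixel_scale > 0, "pixel_scale", "must be > 0")
  check_field(length(cfg$arena_size) == 2 && all(cfg$arena_size >= 16),
              "arena_size", "must be two dimensions, each >= 16 px")
  check_field(cfg$run_speed >= 0, "run_speed", "must be >= 0")
  check_field(cfg$heading_noise >= 0, "heading_noise", "must be >= 0")
  check_field(cfg$body_length_px > 0, "body_length_px", "must be > 0")
  check_field(cfg$n_teleports >= 0, "n_teleports", "must be >= 0")
  check_field(cfg$teleport_min_displacement > 0.5, "teleport_min_displacement",
              "must exceed 0.5 body lengths so teleports trip the exclusion rule")
  check_field(cfg$head_cast_speed_frac >= 0, "head_cast_speed_frac",
              "must be >= 0")
  if (!is.null(cfg$mode_sequence)) {
    check_field(all(cfg$mode_sequence %in% crawl_modes), "mode_sequence",
                paste("modes must be among:", paste(crawl_modes, collapse = ", ")))
    check_field(length(cfg$mode_sequence) %in% c(1L, cfg$n_frames),
                "mode_sequence", "must have length 1 or n_frames")
  }
  rs <- rowSums(cfg$transition)
  check_field(all(abs(rs - 1) < 1e-8) && all(cfg$transition >= 0),
              "transition", "rows must be non-negative and sum to 1")
  check_field(cfg$n_teleports <= cfg$n_frames - 2, "n_teleports",
              "needs n_frames - 2 or fewer teleports")
  cfg
}

check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    abort(sprintf("Invalid configuration: `%s` %s.", field, msg),
          class = "larvatrack_config_error")
  }
  invisible(TRUE)
}

#' Video rendering configuration
#'
#' Controls how a ground-truth track is rasterized into a grayscale frame
#' stack: a filled ellipse (the larva) on a noisy background, with optional
#' distractor blobs to exercise the tracker's multiple-object rejection.
#' Intensities are 8-bit gray levels (0-255).
#'
#' @param larva_axes Semi-major and semi-minor axes of the larva ellipse in
#'   pixels, or `NULL` to derive a 3:1 ellipse from the track's body length.
#' @param foreground_intensity,background_intensity Gray levels of larva and
#'   background. Their difference must exceed `3 * noise_sd` so fixtures are
#'   guaranteed segmentable.
#' @param noise_sd Additive Gaussian pixel noise SD, gray levels.
#' @param polarity `"dark-on-light"` (default; bright-field appearance) or
#'   `"light-on-dark"`.
#' @param n_distractors Number of static disc-shaped distractor blobs.
#' @param distractor_area Distractor area in square pixels.
#' @param distractor_frames Frames (1-based indices) in which distractors are
#'   drawn; `NULL` means all frames.
#' @param seed Integer seed for noise and distractor placement.
#'
#' @return An object of class `render_config`.
#' @seealso [render_video()]
#' @export
render_config <- function(larva_axes = NULL,
                          foreground_intensity = 60,
                          background_intensity = 200,
                          noise_sd = 8,
                          polarity = c("dark-on-light", "light-on-dark"),
                          n_distractors = 0,
                          distractor_area = 120,
                          distractor_frames = NULL,
                          seed = 1L) {
  rc <- list(
    larva_axes = larva_axes,
    foreground_intensity = foreground_intensity,
    background_intensity = background_intensity,
    noise_sd = noise_sd,
    polarity = match.arg(polarity),
    n_distractors = as.integer(n_distractors),
    distractor_area = distractor_area,
    distractor_frames = distractor_frames,
    seed = as.integer(seed)
  )
  class(rc) <- "render_config"
  validate_render_config(rc)
}

validate_render_config <- function(rc) {
  check_field(rc$noise_sd >= 0, "noise_sd", "must be >= 0")
  check_field(
    abs(rc$foreground_intensity - rc$background_intensity) > 3 * rc$noise_sd,
    "noise_sd",
    "foreground/background contrast must exceed 3 x noise_sd")
  check_field(rc$n_distractors >= 0, "n_distractors", "must be >= 0")
  check_field(rc$distractor_area > 0, "distractor_area", "must be > 0")
  if (!is.null(rc$larva_axes)) {
    check_field(length(rc$larva_axes) == 2 && all(rc$larva_axes > 0) &&
                  rc$larva_axes[1] >= rc$larva_axes[2],
                "larva_axes", "must be c(semi_major, semi_minor), both > 0")
  }
  rc
}

#' Screen simulation configuration
#'
#' Parameters of the paired permissive/restrictive screen generator. Defaults
#' match the assay's control behavior: per-larva mean crawl speed 65 um/sec
#' (SD 47) at the permissive temperature, increasing roughly 1.5-fold on the
#' shift to the restrictive temperature. Planted "slow" genotypes get a
#' smaller fold change.
#'
#' @param n_genotypes Number of experimental genotypes (control is extra).
#' @param n_control_larvae,n_larvae_per_genotype Larvae per group.
#' @param control_permissive_mean,control_permissive_sd Mean and SD of
#'   per-larva permissive-temperature speeds, um/sec.
#' @param control_fold_change Restrictive/permissive speed ratio for control
#'   and non-slow genotypes.
#' @param slow_genotype_indices Integer indices (in `1:n_genotypes`) of the
#'   planted slow genotypes.
#' @param slow_fold_change Fold change of planted slow genotypes; must be
#'   below `control_fold_change`.
#' @param restrictive_noise_sd SD of the multiplicative noise applied to the
#'   restrictive-temperature speed (mean-1 lognormal factor).
#' @param speed_noise_model `"lognormal"` (default; matches the requested
#'   mean and SD exactly and is positive by construction) or
#'   `"normal-truncated-at-zero"` (rejection-sampled; truncation pulls the
#'   realized mean slightly above the nominal one).
#' @param seed Integer seed.
#'
#' @return An object of class `screen_sim_config`.
#' @seealso [simulate_screen()]
#' @export
screen_sim_config <- function(n_genotypes = 10,
                              n_control_larvae = 10,
                              n_larvae_per_genotype = 10,
                              control_permissive_mean = 65,
                              control_permissive_sd = 47,
                              control_fold_change = 1.5,
                              slow_genotype_indices = integer(),
                              slow_fold_change = 1.0,
                              restrictive_noise_sd = 0.1,
                              speed_noise_model = c("lognormal",
                                                    "normal-truncated-at-zero"),
                              seed = 1L) {
  cfg <- list(
    n_genotypes = as.integer(n_genotypes),
    n_control_larvae = as.integer(n_control_larvae),
    n_larvae_per_genotype = as.integer(n_larvae_per_genotype),
    control_permissive_mean = control_permissive_mean,
    control_permissive_sd = control_permissive_sd,
    control_fold_change = control_fold_change,
    slow_genotype_indices = as.integer(slow_genotype_indices),
    slow_fold_change = slow_fold_change,
    restrictive_noise_sd = restrictive_noise_sd,
    speed_noise_model = match.arg(speed_noise_model),
    seed = as.integer(seed)
  )
  class(cfg) <- "screen_sim_config"
  validate_screen_sim_config(cfg)
}

validate_screen_sim_config <- function(cfg) {
  check_field(cfg$n_genotypes >= 0, "n_genotypes", "must be >= 0")
  check_field(cfg$n_control_larvae >= 2, "n_control_larvae", "must be >= 2")
  check_field(cfg$n_larvae_per_genotype >= 2, "n_larvae_per_genotype",
              "must be >= 2")
  check_field(cfg$control_permissive_mean > 0, "control_permissive_mean",
              "must be > 0")
  check_field(cfg$control_permissive_sd >= 0, "control_permissive_sd",
              "must be >= 0")
  check_field(cfg$control_fold_change > 0, "control_fold_change", "must be > 0")
  check_field(cfg$slow_fold_change > 0, "slow_fold_change", "must be > 0")
  check_field(cfg$slow_fold_change < cfg$control_fold_change,
              "slow_fold_change", "must be below control_fold_change")
  check_field(cfg$restrictive_noise_sd >= 0, "restrictive_noise_sd",
              "must be >= 0")
  check_field(all(cfg$slow_genotype_indices %in% seq_len(cfg$n_genotypes)),
              "slow_genotype_indices", "must index into 1:n_genotypes")
  cfg
}
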