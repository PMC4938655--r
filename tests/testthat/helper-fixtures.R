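# Fixture builders shared across test files. Everything is generated in
# code; no image files are stored.

# noise-free frame with brute-force rasterized discs (independent of the
# package's own ellipse rasterizer)
disc_frame <- function(h = 100, w = 100, centers = list(c(50, 50)), radius = 5,
                       fg = 60, bg = 200) {
  f <- matrix(bg, h, w)
  for (ct in centers) {
    for (r in seq_len(h)) {
      for (c in seq_len(w)) {
        if ((c - ct[1])^2 + (r - ct[2])^2 <= radius^2) f[r, c] <- fg
      }
    }
  }
  f
}

disc_area <- function(radius) {
  sum(outer(-ceiling(radius):ceiling(radius),
            -ceiling(radius):ceiling(radius),
            function(r, c) r^2 + c^2 <= radius^2))
}

# constant-velocity ground-truth track in a roomy arena (no reflections)
straight_track <- function(n_frames = 100, run_speed = 100, seed = 1,
                           frame_rate = 4, pixel_scale = 10,
                           arena = c(1000, 1000), n_teleports = 0) {
  simulate_trajectory(kinematics_config(
    n_frames = n_frames, mode_sequence = "run_forward",
    run_speed = run_speed, heading_noise = 0, frame_rate = frame_rate,
    pixel_scale = pixel_scale, arena_size = arena,
    n_teleports = n_teleports, seed = seed
  ))
}

# hand-built trajectory from explicit centroids
manual_trajectory <- function(xy, status = NULL, frame_rate = 4,
                              pixel_scale = 10, area = 80) {
  n <- nrow(xy)
  status <- status %||% rep("ok", n)
  new_trajectory(
    tibble::tibble(frame = seq_len(n), status = status,
                   x_px = ifelse(status == "ok", xy[, 1], NA_real_),
                   y_px = ifelse(status == "ok", xy[, 2], NA_real_),
                   area_px2 = ifelse(status == "ok", area, NA_real_)),
    frame_rate = frame_rate, pixel_scale = pixel_scale
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
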