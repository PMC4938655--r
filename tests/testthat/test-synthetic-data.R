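test_that("constant-velocity runs advance exactly speed/frame_rate/pixel_scale px per frame", {
  trk <- straight_track(n_frames = 20, run_speed = 100, frame_rate = 4,
                        pixel_scale = 10, seed = 5)
  steps <- sqrt(diff(trk$x_px)^2 + diff(trk$y_px)^2)
  expect_equal(steps, rep(2.5, 19), tolerance = 1e-12)
  expect_equal(trk$speed_um_s, rep(100, 20))
})

test_that("pause-only tracks stay put with zero true speed", {
  trk <- simulate_trajectory(kinematics_config(n_frames = 12,
                                               mode_sequence = "pause",
                                               seed = 2))
  expect_equal(length(unique(trk$x_px)), 1)
  expect_equal(length(unique(trk$y_px)), 1)
  expect_equal(trk$speed_um_s, rep(0, 12))
})

test_that("injected teleports are counted and exceed the required displacement", {
  for (seed in 1:5) {
    trk <- straight_track(n_frames = 80, seed = seed, n_teleports = 2)
    tf <- attr(trk, "teleport_frames")
    expect_length(tf, 2)
    expect_identical(which(trk$is_teleport), tf)
    # recompute displacements directly from the returned centroids
    jumps <- sqrt((trk$x_px[tf + 1] - trk$x_px[tf])^2 +
                    (trk$y_px[tf + 1] - trk$y_px[tf])^2)
    expect_true(all(jumps > attr(trk, "body_length_px")))
  }
})

test_that("true speed series integrates to the traveled path length", {
  for (seed in 1:6) {
    cfg <- kinematics_config(n_frames = 150, arena_size = c(500, 500),
                             run_speed = 80, seed = seed)
    trk <- simulate_trajectory(cfg)
    path <- sum(sqrt(diff(trk$x_px)^2 + diff(trk$y_px)^2)) *
      cfg$pixel_scale
    integral <- sum(head(trk$speed_um_s, -1)) / cfg$frame_rate
    expect_equal(integral, path, tolerance = 1e-6)
  }
})

test_that("trajectories honor the arena and are seed-deterministic", {
  cfg <- kinematics_config(n_frames = 400, seed = 9, n_teleports = 3)
  trk1 <- simulate_trajectory(cfg)
  trk2 <- simulate_trajectory(cfg)
  expect_identical(as.data.frame(trk1), as.data.frame(trk2))
  trk3 <- simulate_trajectory(kinematics_config(n_frames = 400, seed = 10,
                                                n_teleports = 3))
  expect_false(identical(trk1$x_px, trk3$x_px))
  expect_true(all(trk1$x_px >= 1 & trk1$x_px <= cfg$arena_size[1]))
  expect_true(all(trk1$y_px >= 1 & trk1$y_px <= cfg$arena_size[2]))
})

test_that("invalid kinematics configurations name the offending field", {
  expect_error(kinematics_config(frame_rate = 0), "frame_rate")
  expect_error(kinematics_config(n_frames = 1), "n_frames")
  expect_error(kinematics_config(run_speed = -1), "run_speed")
  expect_error(kinematics_config(teleport_min_displacement = 0.4),
               "teleport_min_displacement")
  expect_error(kinematics_config(mode_sequence = c("crawl")), "mode_sequence")
})

test_that("rendered ellipse area matches the analytic ellipse", {
  trk <- straight_track(n_frames = 3, seed = 4, arena = c(200, 200))
  vid <- render_video(trk, render_config(larva_axes = c(8, 3), noise_sd = 0,
                                         seed = 1))
  f <- vid$frames[[1]]
  mask <- f < (60 + 200) / 2
  oracle <- flood_fill_components(mask)
  expect_equal(oracle$n, 1)
  expect_lt(abs(oracle$areas[1] - pi * 8 * 3) / (pi * 8 * 3), 0.1)
})

test_that("rendering is deterministic and fails when the larva leaves the frame", {
  trk <- straight_track(n_frames = 5, seed = 3)
  rc <- render_config(noise_sd = 5, seed = 8)
  v1 <- render_video(trk, rc)
  v2 <- render_video(trk, rc)
  expect_identical(v1$frames, v2$frames)

  tight <- simulate_trajectory(kinematics_config(
    n_frames = 4, mode_sequence = "pause", arena_size = c(60, 60),
    body_length_px = 10, seed = 1))
  expect_error(render_video(tight, render_config(larva_axes = c(40, 10),
                                                 noise_sd = 0)),
               "frame", class = "larvatrack_render_error")
})

test_that("polarity flip yields the same tracked centroids", {
  trk <- straight_track(n_frames = 8, seed = 6)
  dark <- render_video(trk, render_config(noise_sd = 0, seed = 1))
  light <- render_video(trk, render_config(
    noise_sd = 0, seed = 1, polarity = "light-on-dark",
    foreground_intensity = 200, background_intensity = 60))
  sp <- segmentation_params(expected_area = attr(trk, "body_area_px"),
                            polarity = "auto")
  td <- track_video(dark, sp)
  tl <- track_video(light, sp)
  expect_true(all(td$status == "ok") && all(tl$status == "ok"))
  # 8-bit quantization makes Otsu only bin-level symmetric under inversion,
  # so centroids agree to a small fraction of a pixel, not bit-exactly
  expect_lt(max(abs(td$x_px - tl$x_px)), 0.2)
  expect_lt(max(abs(td$y_px - tl$y_px)), 0.2)
})

test_that("noise-free screens produce the exact normalized changes", {
  sim <- simulate_screen(screen_sim_config(
    n_genotypes = 2, slow_genotype_indices = 1, slow_fold_change = 1.0,
    control_permissive_sd = 0, restrictive_noise_sd = 0, seed = 1))
  wide <- tidyr::pivot_wider(sim$speeds[c("genotype", "larva_id",
                                          "temperature", "mean_speed_um_s")],
                             names_from = "temperature",
                             values_from = "mean_speed_um_s")
  n <- normalized_change(wide$restrictive, wide$permissive)
  expect_equal(n[wide$genotype == "control"], rep(0.5, 10))
  expect_equal(n[wide$genotype == "G001"], rep(0, 10))
  expect_equal(n[wide$genotype == "G002"], rep(0.5, 10))
})

test_that("control permissive speeds center on the configured mean", {
  speeds <- unlist(lapply(1:100, function(s) {
    sim <- simulate_screen(screen_sim_config(n_genotypes = 0, seed = s))
    sim$speeds$mean_speed_um_s[sim$speeds$temperature == "permissive"]
  }))
  se <- 47 / sqrt(length(speeds))
  expect_lt(abs(mean(speeds) - 65), 3 * se)
})

test_that("an empty screen keeps a valid schema", {
  sim <- simulate_screen(screen_sim_config(n_genotypes = 0, seed = 1))
  expect_setequal(unique(sim$speeds$genotype), "control")
  expect_named(sim$speeds, c("genotype", "larva_id", "recording_id",
                             "temperature_C", "temperature",
                             "mean_speed_um_s"))
  expect_equal(nrow(sim$truth), 1)
})

test_that("track and screen tables round-trip through their file formats", {
  trk <- straight_track(n_frames = 10, seed = 2, n_teleports = 1)
  path <- tempfile(fileext = ".csv")
  write_track(trk, path)
  back <- read_track(path)
  cols <- c("frame", "x_px", "y_px", "heading", "mode", "speed_um_s",
            "is_teleport")
  expect_equal(as.data.frame(back)[cols], as.data.frame(trk)[cols],
               tolerance = 1e-12)
  expect_equal(attr(back, "teleport_frames"), attr(trk, "teleport_frames"))
  expect_equal(attr(back, "body_area_px"), attr(trk, "body_area_px"))
  expect_equal(attr(back, "pixel_scale"), attr(trk, "pixel_scale"))

  sim <- simulate_screen(screen_sim_config(n_genotypes = 2, seed = 3))
  sp <- tempfile(fileext = ".csv")
  write_screen_speeds(sim$speeds, sp)
  back2 <- read_screen_speeds(sp)
  expect_equal(back2$mean_speed_um_s, sim$speeds$mean_speed_um_s,
               tolerance = 1e-12)
  expect_equal(back2$temperature, sim$speeds$temperature)
})

test_that("frame stacks round-trip through 8-bit TIFF", {
  trk <- straight_track(n_frames = 4, seed = 7)
  vid <- render_video(trk, render_config(noise_sd = 6, seed = 2))
  path <- tempfile(fileext = ".tif")
  write_frame_stack(vid, path)
  back <- read_frame_stack(path)
  expect_identical(back$frames, vid$frames)
  expect_equal(back$frame_rate, vid$frame_rate)
  expect_equal(back$pixel_scale, vid$pixel_scale)
})
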