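test_that("a single disc is detected with its centroid and rasterized area", {
  f <- disc_frame(centers = list(c(50, 50)), radius = 5)
  res <- segment_frame(f, segmentation_params(expected_area = 78,
                                              area_tolerance = 0.3,
                                              blur_sigma = 1,
                                              closing_radius = 1))
  expect_equal(res$status, "ok")
  expect_equal(res$x_px, 50, tolerance = 0.05)
  expect_equal(res$y_px, 50, tolerance = 0.05)
  expect_gte(res$area_px2, 71)
  expect_lte(res$area_px2, 87)
})

test_that("two size-gate candidates yield multiple_objects with no centroid", {
  f <- disc_frame(centers = list(c(30, 30), c(70, 70)), radius = 5)
  res <- segment_frame(f, segmentation_params(expected_area = 78,
                                              area_tolerance = 0.3))
  expect_equal(res$status, "multiple_objects")
  expect_true(is.na(res$x_px) && is.na(res$area_px2))
})

test_that("degenerate frames are rejected or flagged", {
  params <- segmentation_params(expected_area = 78)
  expect_equal(segment_frame(matrix(128, 50, 50), params)$status, "no_object")
  expect_error(segment_frame(array(1, c(2, 2, 2)), params),
               class = "larvatrack_input_error")
  expect_error(segment_frame(matrix(numeric(0), 0, 0), params),
               class = "larvatrack_input_error")
})

test_that("segmentation is translation-equivariant for integer shifts", {
  f <- disc_frame(h = 90, w = 110, centers = list(c(40, 45)), radius = 6)
  params <- segmentation_params(expected_area = disc_area(6),
                                area_tolerance = 0.4)
  base <- segment_frame(f, params)
  for (shift in list(c(7, 11), c(-5, 3))) {
    g <- disc_frame(h = 90, w = 110,
                    centers = list(c(40 + shift[1], 45 + shift[2])),
                    radius = 6)
    res <- segment_frame(g, params)
    expect_equal(res$x_px - base$x_px, shift[1], tolerance = 1e-9)
    expect_equal(res$y_px - base$y_px, shift[2], tolerance = 1e-9)
    expect_equal(res$area_px2, base$area_px2)
  }
})

test_that("auto polarity is invariant to intensity inversion", {
  f <- disc_frame(centers = list(c(42, 57)), radius = 6)
  params <- segmentation_params(expected_area = disc_area(6),
                                area_tolerance = 0.4, polarity = "auto")
  a <- segment_frame(f, params)
  b <- segment_frame(255 - f, params)
  expect_equal(a$status, "ok")
  expect_equal(b$status, "ok")
  expect_equal(a$x_px, b$x_px, tolerance = 1e-6)
  expect_equal(a$y_px, b$y_px, tolerance = 1e-6)
})

test_that("re-segmenting the binary mask reproduces the same component", {
  f <- disc_frame(centers = list(c(50, 50)), radius = 6)
  params <- segmentation_params(expected_area = disc_area(6),
                                area_tolerance = 0.4, blur_sigma = 0,
                                closing_radius = 0)
  first <- segment_frame(f, params)
  mask <- matrix(0, nrow(f), ncol(f))
  mask[f < 128] <- 255 # the mask the gate accepted, as a binary image
  second <- segment_frame(255 - mask, params)
  expect_equal(second$status, "ok")
  expect_equal(second$x_px, first$x_px)
  expect_equal(second$y_px, first$y_px)
  expect_equal(second$area_px2, first$area_px2)
})

test_that("component labeling matches the flood-fill oracle on random masks", {
  set.seed(42)
  for (i in 1:25) {
    mask <- matrix(runif(48 * 64) > 0.72, 48, 64)
    mine <- larvatrack:::label_components(mask)
    oracle <- flood_fill_components(mask)
    expect_equal(mine$n, oracle$n)
    expect_identical(partition_signature(mine$labels),
                     partition_signature(oracle$labels))
    ord_m <- order(mine$centroids[, 1], mine$centroids[, 2])
    ord_o <- order(oracle$centroids[, 1], oracle$centroids[, 2])
    expect_equal(mine$centroids[ord_m, , drop = FALSE],
                 oracle$centroids[ord_o, , drop = FALSE],
                 ignore_attr = TRUE)
    expect_equal(sort(mine$areas), sort(oracle$areas))
  }
})

test_that("tracking a noise-free rendered video recovers every true centroid", {
  trk <- straight_track(n_frames = 40, seed = 11, arena = c(300, 300))
  vid <- render_video(trk, render_config(noise_sd = 0, seed = 1))
  traj <- track_video(vid, segmentation_params(
    expected_area = attr(trk, "body_area_px")))
  expect_true(all(traj$status == "ok"))
  err <- sqrt((traj$x_px - trk$x_px)^2 + (traj$y_px - trk$y_px)^2)
  expect_lt(sqrt(mean(err^2)), 0.5)
})

test_that("occluded and distractor frames are flagged, never interpolated", {
  trk <- straight_track(n_frames = 30, seed = 12, arena = c(300, 300))
  vid <- render_video(trk, render_config(noise_sd = 0, seed = 1))
  vid$frames[[15]] <- matrix(200L, nrow(vid$frames[[1]]),
                             ncol(vid$frames[[1]]))
  traj <- track_video(vid, segmentation_params(
    expected_area = attr(trk, "body_area_px")))
  expect_equal(traj$status[15], "no_object")
  expect_true(all(traj$status[-15] == "ok"))
  expect_true(is.na(traj$x_px[15]))

  area <- attr(trk, "body_area_px")
  vid2 <- render_video(trk, render_config(noise_sd = 0, seed = 2,
                                          n_distractors = 1,
                                          distractor_area = area,
                                          distractor_frames = 10:20))
  traj2 <- track_video(vid2, segmentation_params(expected_area = area))
  expect_true(all(traj2$status[10:20] == "multiple_objects"))
  expect_true(all(traj2$status[-(10:20)] == "ok"))
})

test_that("frame-shape mismatches are reported with the frame index", {
  trk <- straight_track(n_frames = 5, seed = 13)
  vid <- render_video(trk, render_config(noise_sd = 0, seed = 1))
  vid$frames[[3]] <- vid$frames[[3]][-1, ]
  expect_error(track_video(vid, segmentation_params(expected_area = 100)),
               "3", class = "larvatrack_input_error")
})

test_that("trajectories round-trip through CSV", {
  trk <- straight_track(n_frames = 10, seed = 14)
  traj <- as_trajectory(trk)
  path <- tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(as.data.frame(back), as.data.frame(traj), tolerance = 1e-12)
  expect_equal(attr(back, "frame_rate"), attr(traj, "frame_rate"))
})
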