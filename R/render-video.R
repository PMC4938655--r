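# Rasterizes ground-truth tracks into 8-bit grayscale frame stacks: a filled
# ellipse on a noisy background, matching the appearance of a dark larva
# under bright-field illumination at low magnification.

#' Render a ground-truth track as a grayscale frame stack
#'
#' Draws the larva as a filled ellipse centered on each frame's true centroid
#' and oriented along the true heading, adds optional static distractor
#' blobs, then additive Gaussian pixel noise, and quantizes to 8-bit gray
#' levels. Distractor discs are placed uniformly at random, rejecting
#' positions that would touch the larva in any frame where the distractor is
#' drawn (overlapping blobs would merge into one object and change the
#' scene's ground truth).
#'
#' @param track A `larva_track` from [simulate_trajectory()].
#' @param rc A [render_config()].
#'
#' @return A `frame_stack`: list with `frames` (list of integer matrices,
#'   rows = y, columns = x, values 0-255), `frame_rate`, `pixel_scale` and
#'   `polarity`. Deterministic for a fixed `rc$seed`.
#' @export
#' @examples
#' trk <- simulate_trajectory(kinematics_config(n_frames = 5, seed = 1))
#' vid <- render_video(trk, render_config(noise_sd = 0, seed = 1))
#' dim(vid$frames[[1]])
render_video <- function(track, rc = render_config()) {
  rc <- validate_render_config(rc)
  if (rc$polarity == "dark-on-light" &&
      rc$foreground_intensity >= rc$background_intensity) {
    abort("Invalid configuration: `polarity` dark-on-light needs foreground darker than background.")
  }
  if (rc$polarity == "light-on-dark" &&
      rc$foreground_intensity <= rc$background_intensity) {
    abort("Invalid configuration: `polarity` light-on-dark needs foreground brighter than background.")
  }
  cfg <- attr(track, "config")
  w <- cfg$arena_size[1]
  h <- cfg$arena_size[2]
  axes <- rc$larva_axes %||%
    c(attr(track, "body_length_px") / 2, attr(track, "body_length_px") / 6)
  a <- axes[1]
  b <- axes[2]

  out_of_frame <- track$x_px < a + 1 | track$x_px > w - a |
    track$y_px < a + 1 | track$y_px > h - a
  if (any(out_of_frame)) {
    abort(sprintf("Larva out of frame at frame %d.", which(out_of_frame)[1]),
          class = "larvatrack_render_error")
  }

  set.seed(rc$seed)
  n <- nrow(track)
  dframes <- rc$distractor_frames %||% seq_len(n)
  distractors <- place_distractors(rc, track, dframes, w, h, a)

  frames <- vector("list", n)
  for (i in seq_len(n)) {
    f <- matrix(rc$background_intensity, nrow = h, ncol = w)
    if (i %in% dframes && rc$n_distractors > 0) {
      for (d in seq_len(rc$n_distractors)) {
        f <- draw_ellipse(f, distractors$x[d], distractors$y[d],
                          distractors$r[d], distractors$r[d], 0,
                          rc$foreground_intensity)
      }
    }
    f <- draw_ellipse(f, track$x_px[i], track$y_px[i], a, b,
                      track$heading[i], rc$foreground_intensity)
    if (rc$noise_sd > 0) {
      f <- f + matrix(rnorm(h * w, 0, rc$noise_sd), nrow = h)
    }
    frames[[i]] <- matrix(as.integer(pmin(pmax(round(f), 0), 255)), nrow = h)
  }

  structure(
    list(frames = frames,
         frame_rate = attr(track, "frame_rate"),
         pixel_scale = attr(track, "pixel_scale"),
         polarity = rc$polarity),
    class = "frame_stack"
  )
}

place_distractors <- function(rc, track, dframes, w, h, a) {
  if (rc$n_distractors == 0) {
    return(list(x = numeric(), y = numeric(), r = numeric()))
  }
  r <- sqrt(rc$distractor_area / pi)
  xs <- ys <- numeric(rc$n_distractors)
  lx <- track$x_px[dframes]
  ly <- track$y_px[dframes]
  for (d in seq_len(rc$n_distractors)) {
    placed <- FALSE
    for (try in 1:2000) {
      cx <- runif(1, r + 2, w - r - 1)
      cy <- runif(1, r + 2, h - r - 1)
      if (min(sqrt((lx - cx)^2 + (ly - cy)^2)) > a + r + 4) {
        xs[d] <- cx
        ys[d] <- cy
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort("Could not place a distractor away from the larva path; enlarge the arena.",
            class = "larvatrack_render_error")
    }
  }
  list(x = xs, y = ys, r = rep(r, rc$n_distractors))
}

# fill a rotated ellipse into matrix f (rows = y, cols = x, 1-based pixel
# centers at integer coordinates)
draw_ellipse <- function(f, cx, cy, a, b, theta, value) {
  h <- nrow(f)
  w <- ncol(f)
  cmin <- max(1L, floor(cx - a))
  cmax <- min(w, ceiling(cx + a))
  rmin <- max(1L, floor(cy - a))
  rmax <- min(h, ceiling(cy + a))
  cols <- cmin:cmax
  rows <- rmin:rmax
  dx <- outer(rep(1, length(rows)), cols - cx)
  dy <- outer(rows - cy, rep(1, length(cols)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  block <- f[rows, cols, drop = FALSE]
  block[inside] <- value
  f[rows, cols] <- block
  f
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %dx%d px @ %g Hz, %g um/px (%s)\n",
              length(x$frames), d[2], d[1], x$frame_rate, x$pixel_scale,
              x$polarity))
  invisible(x)
}

#' Write / read a frame stack as a multi-page 8-bit grayscale TIFF
#'
#' Acquisition metadata (frame rate, pixel scale, polarity) travels in a
#' JSON sidecar (`<path>.json`) because baseline TIFF has no standard slot
#' for it; [read_frame_stack()] restores it when the sidecar is present and
#' otherwise uses the supplied defaults.
#'
#' @param stack A `frame_stack`.
#' @param path TIFF file path.
#' @param frame_rate,pixel_scale,polarity Metadata defaults used when no
#'   sidecar accompanies the TIFF.
#' @return `write_frame_stack` returns `path` invisibly; `read_frame_stack`
#'   returns a `frame_stack`.
#' @export
write_frame_stack <- function(stack, path) {
  pages <- lapply(stack$frames, function(f) f / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(frame_rate = stack$frame_rate, pixel_scale = stack$pixel_scale,
         polarity = stack$polarity),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path, frame_rate = 4, pixel_scale = 30,
                             polarity = "dark-on-light") {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- list(frame_rate = frame_rate, pixel_scale = pixel_scale,
               polarity = polarity)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE))
  }
  frames <- lapply(pages, function(p) {
    matrix(as.integer(round(p * 255)), nrow = nrow(p))
  })
  structure(
    list(frames = frames, frame_rate = meta$frame_rate,
         pixel_scale = meta$pixel_scale, polarity = meta$polarity),
    class = "frame_stack"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
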