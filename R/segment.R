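# Per-frame single-larva detection. The chain is fixed: Gaussian blur ->
# Otsu threshold on the blurred image -> binarize (larva side chosen by
# polarity) -> morphological closing with a disc -> 8-connected component
# labeling -> size gate around a manually entered expected area. Exactly one
# surviving component is required; zero or several yield no data for that
# frame, which downstream stages treat as missing, never interpolated.
#
# Blur, threshold and closing are delegated to EBImage; component labeling
# is done here because EBImage's bwlabel is 4-connected and the chain
# specifies 8-connectivity.

#' Segmentation parameters
#'
#' @param expected_area Expected larva area in square pixels ("manually
#'   entered size"); components outside
#'   `expected_area * [1 - area_tolerance, 1 + area_tolerance]` are rejected.
#' @param blur_sigma Gaussian blur SD in pixels ("mild" blur; 0 disables).
#' @param closing_radius Radius of the disc structuring element for
#'   morphological closing, pixels (0 disables).
#' @param area_tolerance Relative half-width of the size gate, in (0, 1).
#' @param polarity Which intensity side is the larva: `"auto"` (the side
#'   with fewer pixels after thresholding — the animal is small relative to
#'   the arena), `"dark-on-light"` or `"light-on-dark"`.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(expected_area,
                                blur_sigma = 2,
                                closing_radius = 2,
                                area_tolerance = 0.5,
                                polarity = c("auto", "dark-on-light",
                                             "light-on-dark")) {
  p <- list(expected_area = expected_area, blur_sigma = blur_sigma,
            closing_radius = as.integer(closing_radius),
            area_tolerance = area_tolerance, polarity = match.arg(polarity))
  class(p) <- "segmentation_params"
  check_field(p$expected_area > 0, "expected_area", "must be > 0")
  check_field(p$blur_sigma >= 0, "blur_sigma", "must be >= 0")
  check_field(p$closing_radius >= 0, "closing_radius", "must be >= 0")
  check_field(p$area_tolerance > 0 && p$area_tolerance < 1, "area_tolerance",
              "must be in (0, 1)")
  p
}

#' Detect the larva in one grayscale frame
#'
#' Runs the blur / Otsu / closing / labeling / size-gate chain on a single
#' frame. Returns data only when exactly one component passes the size gate;
#' a frame with none (`"no_object"`) or several (`"multiple_objects"`)
#' candidate objects is reported as such, with no centroid.
#'
#' @param frame Numeric matrix (rows = y, columns = x). Values may be 8-bit
#'   gray levels (0-255) or already scaled to `[0, 1]`.
#' @param params A [segmentation_params()].
#' @param frame_index Frame number recorded in the result.
#'
#' @return One-row tibble: `frame`, `status` (`"ok"`, `"no_object"` or
#'   `"multiple_objects"`), `x_px`, `y_px` (unweighted mean of member pixel
#'   coordinates, 1-based, x = column, y = row; `NA` unless ok) and
#'   `area_px2` (member pixel count; `NA` unless ok).
#' @export
#' @examples
#' f <- matrix(200, 60, 80)
#' f[25:35, 40:50] <- 60
#' segment_frame(f, segmentation_params(expected_area = 121))
segment_frame <- function(frame, params, frame_index = 1L) {
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0) {
    abort("`frame` must be a non-empty 2-D numeric matrix.",
          class = "larvatrack_input_error")
  }
  mask <- binarize_frame(frame, params)
  if (is.null(mask)) {
    return(seg_row(frame_index, "no_object"))
  }
  lab <- label_components(mask)
  if (lab$n == 0) {
    return(seg_row(frame_index, "no_object"))
  }
  lo <- params$expected_area * (1 - params$area_tolerance)
  hi <- params$expected_area * (1 + params$area_tolerance)
  pass <- which(lab$areas >= lo & lab$areas <= hi)
  if (length(pass) == 0) {
    return(seg_row(frame_index, "no_object"))
  }
  if (length(pass) > 1) {
    return(seg_row(frame_index, "multiple_objects"))
  }
  seg_row(frame_index, "ok",
          x = lab$centroids[pass, 1], y = lab$centroids[pass, 2],
          area = lab$areas[pass])
}

seg_row <- function(frame_index, status, x = NA_real_, y = NA_real_,
                    area = NA_real_) {
  tibble::tibble(frame = as.integer(frame_index), status = status,
                 x_px = unname(x), y_px = unname(y),
                 area_px2 = as.numeric(area))
}

# blur + Otsu + polarity + closing; returns a logical foreground mask, or
# NULL when the (blurred) frame is constant and Otsu is undefined
binarize_frame <- function(frame, params) {
  f <- if (max(frame) > 1) frame / 255 else frame
  if (params$blur_sigma > 0) {
    # cap the kernel so small test frames remain blurrable
    radius <- min(2L * as.integer(ceiling(3 * params$blur_sigma)) + 1L,
                  odd_below(min(dim(f))))
    f <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(f),
                                           sigma = params$blur_sigma,
                                           radius = radius,
                                           boundary = "replicate"))
  }
  if (diff(range(f)) < 1e-12) {
    return(NULL)
  }
  thr <- EBImage::otsu(EBImage::as.Image(f), range = c(0, 1), levels = 256)
  light <- f > thr
  mask <- switch(params$polarity,
    "dark-on-light" = !light,
    "light-on-dark" = light,
    auto = if (sum(light) <= sum(!light)) light else !light
  )
  if (params$closing_radius > 0) {
    kern <- EBImage::makeBrush(2L * params$closing_radius + 1L, shape = "disc")
    mask <- EBImage::imageData(EBImage::closing(mask, kern)) > 0
  }
  mask
}

odd_below <- function(k) if (k %% 2L == 1L) k else k - 1L

# 8-connected component labeling by union-find over foreground pixels.
# Returns n (component count), areas, and centroids (n x 2, columns x, y).
label_components <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  fg <- which(mask)
  k <- length(fg)
  if (k == 0) {
    return(list(n = 0L, areas = numeric(), centroids = matrix(0, 0, 2),
                labels = matrix(0L, h, w)))
  }
  id <- integer(h * w) # linear index -> compact foreground id
  id[fg] <- seq_len(k)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  # union with the four already-scanned neighbors in column-major order:
  # up in this column, and up/same/down in the previous column
  ndr <- c(-1L, -1L, 0L, 1L)
  ndc <- c(0L, -1L, -1L, -1L)
  for (j in seq_len(k)) {
    r <- rows[j]
    c <- cols[j]
    for (t in 1:4) {
      rr <- r + ndr[t]
      cc <- c + ndc[t]
      if (rr < 1L || rr > h || cc < 1L) next
      qi <- id[(cc - 1L) * h + rr]
      if (qi > 0L) {
        ra <- find(j)
        rb <- find(qi)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  labs <- match(roots, unique(roots))
  n <- max(labs)
  areas <- tabulate(labs, n)
  cx <- vapply(seq_len(n), function(l) mean(cols[labs == l]), numeric(1))
  cy <- vapply(seq_len(n), function(l) mean(rows[labs == l]), numeric(1))
  lab_mat <- matrix(0L, h, w)
  lab_mat[fg] <- labs
  list(n = n, areas = areas, centroids = cbind(x = cx, y = cy),
       labels = lab_mat)
}

#' Track a larva through a frame stack
#'
#' Applies [segment_frame()] to every frame, in order. Frames where
#' detection fails keep their status flag and contribute no centroid;
#' nothing is interpolated.
#'
#' @param stack A `frame_stack` (see [render_video()] /
#'   [read_frame_stack()]).
#' @param params A [segmentation_params()].
#'
#' @return A `larva_trajectory`: tibble with one row per frame (`frame`,
#'   `status`, `x_px`, `y_px`, `area_px2`) carrying `frame_rate` and
#'   `pixel_scale` attributes from the stack metadata.
#' @export
track_video <- function(stack, params) {
  frames <- stack$frames
  if (length(frames) == 0) {
    abort("`stack` has no frames.", class = "larvatrack_input_error")
  }
  d1 <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d1)) {
      abort(sprintf("Frame %d has a different shape than frame 1.", i),
            class = "larvatrack_input_error")
    }
  }
  res <- dplyr::bind_rows(
    lapply(seq_along(frames), function(i) {
      segment_frame(frames[[i]], params, frame_index = i)
    })
  )
  new_trajectory(res, frame_rate = stack$frame_rate,
                 pixel_scale = stack$pixel_scale)
}

#' Construct a trajectory from per-frame detections
#'
#' @param detections Tibble with columns `frame`, `status`, `x_px`, `y_px`,
#'   `area_px2`.
#' @param frame_rate Acquisition rate, Hz.
#' @param pixel_scale Micrometres per pixel.
#' @return A `larva_trajectory` tibble.
#' @export
new_trajectory <- function(detections, frame_rate, pixel_scale) {
  check_field(frame_rate > 0, "frame_rate", "must be > 0")
  check_field(pixel_scale > 0, "pixel_scale", "must be > 0")
  structure(tibble::as_tibble(detections),
            class = c("larva_trajectory", class(tibble::tibble())),
            frame_rate = frame_rate, pixel_scale = pixel_scale)
}

#' Treat a ground-truth track as a perfectly tracked trajectory
#'
#' Bypasses rendering and segmentation: every frame becomes an ok detection
#' at the true centroid with the track's nominal body area. Useful for
#' testing the kinematics stage against known ground truth.
#'
#' @param track A `larva_track`.
#' @return A `larva_trajectory`.
#' @export
as_trajectory <- function(track) {
  new_trajectory(
    tibble::tibble(frame = track$frame, status = "ok",
                   x_px = track$x_px, y_px = track$y_px,
                   area_px2 = attr(track, "body_area_px")),
    frame_rate = attr(track, "frame_rate"),
    pixel_scale = attr(track, "pixel_scale")
  )
}

#' Write / read a trajectory as CSV
#'
#' Columns: `frame`, `status`, `x_px`, `y_px`, `area_px2`; frame rate and
#' pixel scale go into a JSON sidecar.
#'
#' @param traj A `larva_trajectory`.
#' @param path CSV file path.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  jsonlite::write_json(
    list(frame_rate = attr(traj, "frame_rate"),
         pixel_scale = attr(traj, "pixel_scale")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_trajectory(tibble::as_tibble(read.csv(path)),
                 frame_rate = meta$frame_rate, pixel_scale = meta$pixel_scale)
}
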