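# Speed and length quantification. Instantaneous speed is the centroid
# displacement between consecutive ok frames divided by the frame interval;
# pairs whose displacement exceeds half the larva's body length are excluded
# as manual-repositioning artifacts; up to three recordings per larva are
# pooled at the level of individual instantaneous speeds.

#' Instantaneous speeds from a trajectory
#'
#' One entry per pair of consecutive ok frames whose frame indices differ by
#' exactly 1; pairs spanning a failed detection contribute nothing. Speed is
#' the Euclidean centroid displacement converted to micrometres, times the
#' frame rate.
#'
#' @param traj A `larva_trajectory`.
#' @return Tibble with columns `pair_index` (frame number of the first frame
#'   of the pair), `displacement_um` and `speed_um_s`. Empty (not an error)
#'   when fewer than two adjacent ok frames exist.
#' @export
#' @examples
#' traj <- new_trajectory(
#'   tibble::tibble(frame = 1:2, status = "ok", x_px = c(0, 3),
#'                  y_px = c(0, 4), area_px2 = 80),
#'   frame_rate = 4, pixel_scale = 10)
#' instantaneous_speeds(traj) # 5 px * 10 um/px * 4 Hz = 200 um/s
instantaneous_speeds <- function(traj) {
  frame_rate <- attr(traj, "frame_rate")
  pixel_scale <- attr(traj, "pixel_scale")
  ok <- traj[traj$status == "ok", , drop = FALSE]
  if (nrow(ok) < 2) {
    return(tibble::tibble(pair_index = integer(), displacement_um = numeric(),
                          speed_um_s = numeric()))
  }
  adjacent <- which(diff(ok$frame) == 1L)
  disp_px <- sqrt(diff(ok$x_px)^2 + diff(ok$y_px)^2)[adjacent]
  tibble::tibble(
    pair_index = ok$frame[adjacent],
    displacement_um = disp_px * pixel_scale,
    speed_um_s = disp_px * pixel_scale * frame_rate
  )
}

#' Larval length from mean blob area
#'
#' The screen's length proxy: the mean segmented area is converted to a
#' length as `sqrt(mean_area / 3.14) * pixel_scale`. The constant 3.14 is
#' used literally, for bit-compatibility with the original screen scripts.
#' Geometrically this is the equivalent-circle radius of the blob, not an
#' ellipse axis; it is a consistent relative scale across larvae, which is
#' all the exclusion rule needs.
#'
#' @param mean_area Mean larva area over ok frames, square pixels.
#' @param pixel_scale Micrometres per pixel.
#' @return Length in micrometres.
#' @export
#' @examples
#' larval_length(314, pixel_scale = 1) # 10
larval_length <- function(mean_area, pixel_scale = 1) {
  if (any(!is.finite(mean_area)) || any(mean_area <= 0)) {
    abort("`mean_area` must be positive.", class = "larvatrack_input_error")
  }
  sqrt(mean_area / 3.14) * pixel_scale
}

#' Exclude implausibly large frame-to-frame displacements
#'
#' Removes speed entries whose displacement exceeds half the larval length
#' (strictly; a displacement of exactly half the length is kept). In the
#' assay these jumps come from the experimenter manually re-centering the
#' animal, not from crawling.
#'
#' @param speed_entries Tibble from [instantaneous_speeds()].
#' @param larval_length_um Body length in micrometres (> 0).
#' @return List with `kept` (entries in original order) and `n_excluded`.
#' @export
apply_exclusion <- function(speed_entries, larval_length_um) {
  check_field(is.finite(larval_length_um) && larval_length_um > 0,
              "larval_length_um", "must be > 0")
  drop <- speed_entries$displacement_um > larval_length_um / 2
  list(kept = speed_entries[!drop, , drop = FALSE],
       n_excluded = sum(drop))
}

#' Summarize one larva at one temperature
#'
#' Pools up to three recordings of the same larva: the body length is
#' computed from the mean ok-frame area across all recordings, the
#' half-body-length exclusion is applied per recording with that single
#' length, and the surviving instantaneous speeds are pooled before taking
#' the mean and sample SD (so recordings contribute in proportion to their
#' usable frame pairs).
#'
#' @param recordings A `larva_trajectory` or list of 1-3 of them sharing the
#'   same pixel scale.
#' @param larva_id Identifier carried into the output.
#' @param temperature_label `"permissive"` or `"restrictive"`.
#'
#' @return One-row tibble: `larva_id`, `temperature`, `mean_speed_um_s`,
#'   `speed_sd_um_s`, `larval_length_um`, `n_speed_samples` (kept pairs),
#'   `n_excluded_pairs`, `n_invalid_frames`, `n_pairs_total` (all
#'   consecutive-frame pairs across recordings) and `n_recordings`.
#'   `mean_speed_um_s` is `NA` when no speed sample survives. Kept pairs,
#'   excluded pairs and pairs lost to failed detections always add up to
#'   `n_pairs_total`.
#' @export
summarize_larva <- function(recordings, larva_id = "larva",
                            temperature_label = c("permissive",
                                                  "restrictive")) {
  temperature_label <- match.arg(temperature_label)
  if (inherits(recordings, "larva_trajectory")) {
    recordings <- list(recordings)
  }
  if (length(recordings) < 1 || length(recordings) > 3) {
    abort("Between 1 and 3 recordings may be pooled per larva.",
          class = "larvatrack_input_error")
  }
  scales <- vapply(recordings, attr, numeric(1), "pixel_scale")
  if (length(unique(scales)) != 1) {
    abort("All pooled recordings must share the same pixel scale.",
          class = "larvatrack_input_error")
  }

  areas <- unlist(lapply(recordings, function(tr) {
    tr$area_px2[tr$status == "ok"]
  }))
  if (length(areas) == 0) {
    return(larva_row(larva_id, temperature_label, NA_real_, NA_real_,
                     NA_real_, 0L, 0L,
                     sum(vapply(recordings, nrow, integer(1))),
                     sum(vapply(recordings, nrow, integer(1)) - 1L),
                     length(recordings)))
  }
  length_um <- larval_length(mean(areas), scales[1])

  kept <- vector("list", length(recordings))
  n_excluded <- 0L
  n_invalid <- 0L
  n_pairs_total <- 0L
  for (i in seq_along(recordings)) {
    tr <- recordings[[i]]
    entries <- instantaneous_speeds(tr)
    excl <- apply_exclusion(entries, length_um)
    kept[[i]] <- excl$kept$speed_um_s
    n_excluded <- n_excluded + excl$n_excluded
    n_invalid <- n_invalid + sum(tr$status != "ok")
    n_pairs_total <- n_pairs_total + max(nrow(tr) - 1L, 0L)
  }
  speeds <- unlist(kept)
  larva_row(
    larva_id, temperature_label,
    mean_speed = if (length(speeds) > 0) mean(speeds) else NA_real_,
    speed_sd = if (length(speeds) > 1) sd(speeds) else NA_real_,
    length_um = length_um,
    n_kept = length(speeds), n_excluded = n_excluded,
    n_invalid = n_invalid, n_pairs = n_pairs_total,
    n_rec = length(recordings)
  )
}

larva_row <- function(larva_id, temperature, mean_speed, speed_sd, length_um,
                      n_kept, n_excluded, n_invalid, n_pairs, n_rec) {
  tibble::tibble(
    larva_id = larva_id, temperature = temperature,
    mean_speed_um_s = mean_speed, speed_sd_um_s = speed_sd,
    larval_length_um = length_um,
    n_speed_samples = as.integer(n_kept),
    n_excluded_pairs = as.integer(n_excluded),
    n_invalid_frames = as.integer(n_invalid),
    n_pairs_total = as.integer(n_pairs),
    n_recordings = as.integer(n_rec)
  )
}

#' Write per-larva summaries as CSV
#'
#' @param summaries Tibble of [summarize_larva()] rows.
#' @param path CSV file path.
#' @export
write_larva_summaries <- function(summaries, path) {
  write.csv(as.data.frame(summaries), path, row.names = FALSE)
  invisible(path)
}
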