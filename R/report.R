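# Reporting: time-lapse path projections, screen-wide fold-change charts and
# speed histograms. Every plotted quantity also exists in an emitted CSV, so
# figures are views over tables, never the only record of a result.

#' Project a trajectory's centroid path over time
#'
#' The low-magnification "crawl pattern" view: all visited centroids joined
#' in time order, with the start of the crawl marked by an asterisk.
#'
#' @param traj A `larva_trajectory` with at least one ok frame.
#' @return A `trajectory_projection`: list with `data` (tibble `frame`,
#'   `t_sec`, `x_px`, `y_px`, `path_um` cumulative path length) and `plot`
#'   (a ggplot).
#' @export
trajectory_projection <- function(traj) {
  ok <- traj[traj$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0) {
    abort("No ok frames: nothing to project.",
          class = "larvatrack_report_error")
  }
  pixel_scale <- attr(traj, "pixel_scale")
  step_um <- c(0, sqrt(diff(ok$x_px)^2 + diff(ok$y_px)^2) * pixel_scale)
  dat <- tibble::tibble(
    frame = ok$frame,
    t_sec = (ok$frame - ok$frame[1]) / attr(traj, "frame_rate"),
    x_px = ok$x_px, y_px = ok$y_px,
    path_um = cumsum(step_um)
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x_px, y = .data$y_px)) +
    ggplot2::geom_path(ggplot2::aes(color = .data$t_sec), linewidth = 0.6) +
    ggplot2::geom_point(data = dat[1, ], shape = 8, size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = "time (s)",
                  title = "Crawl path projection (* = start)") +
    ggplot2::theme_minimal()
  structure(list(data = dat, plot = p), class = "trajectory_projection")
}

#' @export
print.trajectory_projection <- function(x, ...) {
  cat(sprintf("<trajectory_projection> %d centroids, %.0f um path\n",
              nrow(x$data), max(x$data$path_um)))
  print(x$plot)
  invisible(x)
}

#' @export
autoplot.larva_trajectory <- function(object, ...) {
  trajectory_projection(object)$plot
}

#' Fold-change chart for a screen
#'
#' One bar per genotype, control first and experimental genotypes in
#' ascending fold-change order; slow hits highlighted. The underlying table
#' is available via [screen_report()].
#'
#' @param object A `screen_hits` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.screen_hits <- function(object, ...) {
  dat <- fold_change_chart_data(object)
  dat$genotype <- factor(dat$genotype, levels = dat$genotype)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$genotype,
                                    y = .data$fold_change,
                                    fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(control = "#4477AA",
                                          slow = "#CC3311",
                                          not_slow = "grey55")) +
    ggplot2::labs(x = NULL, y = "fold change (restrictive / permissive)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

fold_change_chart_data <- function(hits) {
  cs <- attr(hits, "control_stats")
  ctrl <- tibble::tibble(genotype = cs$genotype,
                         fold_change = cs$fold_change,
                         group = "control")
  if (nrow(hits) == 0) {
    return(ctrl)
  }
  exp_rows <- tibble::tibble(
    genotype = hits$genotype,
    fold_change = hits$fold_change,
    group = ifelse(hits$is_slow, "slow", "not_slow")
  )
  dplyr::bind_rows(ctrl, exp_rows[order(exp_rows$fold_change), ])
}

#' Assemble the screen's report bundle
#'
#' Writes, under `dir`: `hit_calls.csv` (the tidy hit table),
#' `fold_change_chart.csv` (control first, then genotypes by ascending fold
#' change, with hit flags), `speed_histogram.csv` (binned per-larva mean
#' speeds by temperature) and, unless `figures = FALSE`, `fold_change.png`
#' and `speed_histogram.png` rendered from exactly those tables.
#'
#' @param hits A `screen_hits` table from [run_screen()].
#' @param speeds The long speeds tibble the screen was run on (for the
#'   histogram); `NULL` skips the histogram outputs.
#' @param dir Output directory (created if needed).
#' @param binwidth Histogram bin width, um/sec.
#' @param figures Write PNG figures as well as CSVs.
#' @return A `report_bundle`: list of the emitted tables and file paths.
#' @export
screen_report <- function(hits, speeds = NULL, dir = tempfile("report"),
                          binwidth = 25, figures = TRUE) {
  if (!inherits(hits, "screen_hits")) {
    abort("`hits` must come from run_screen().",
          class = "larvatrack_input_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  hit_table <- tidy(hits)
  paths$hit_calls <- file.path(dir, "hit_calls.csv")
  write.csv(as.data.frame(hit_table), paths$hit_calls, row.names = FALSE)

  chart <- fold_change_chart_data(hits)
  paths$fold_change_chart <- file.path(dir, "fold_change_chart.csv")
  write.csv(as.data.frame(chart), paths$fold_change_chart, row.names = FALSE)

  histogram <- NULL
  if (!is.null(speeds)) {
    breaks <- seq(0, max(speeds$mean_speed_um_s) + binwidth, by = binwidth)
    histogram <- dplyr::count(
      dplyr::mutate(
        speeds,
        speed_bin = cut(.data$mean_speed_um_s, breaks = breaks,
                        include.lowest = TRUE, right = FALSE)
      ),
      .data$temperature, .data$speed_bin, name = "n_larvae"
    )
    paths$speed_histogram <- file.path(dir, "speed_histogram.csv")
    write.csv(as.data.frame(histogram), paths$speed_histogram,
              row.names = FALSE)
  }

  if (figures) {
    paths$fold_change_png <- file.path(dir, "fold_change.png")
    ggplot2::ggsave(paths$fold_change_png, autoplot(hits),
                    width = 7, height = 4, dpi = 150)
    if (!is.null(speeds)) {
      hp <- ggplot2::ggplot(speeds,
                            ggplot2::aes(x = .data$mean_speed_um_s,
                                         fill = .data$temperature)) +
        ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                                position = "identity", alpha = 0.6) +
        ggplot2::labs(x = "mean speed (um/s)", y = "larvae") +
        ggplot2::theme_minimal()
      paths$speed_histogram_png <- file.path(dir, "speed_histogram.png")
      ggplot2::ggsave(paths$speed_histogram_png, hp,
                      width = 7, height = 4, dpi = 150)
    }
  }

  manifest <- list(
    alpha = attr(hits, "alpha"),
    control = attr(hits, "control"),
    n_genotypes = nrow(hits),
    n_slow = sum(hits$is_slow),
    files = lapply(paths, basename)
  )
  paths$manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)

  structure(list(dir = dir, hit_table = hit_table, fold_change_chart = chart,
                 speed_histogram = histogram, paths = paths),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %s\n  files: %s\n", x$dir,
              paste(basename(unlist(x$paths)), collapse = ", ")))
  invisible(x)
}
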