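# Hit calling. A genotype is called "slow" when two one-tailed Welch tests
# against the control both reject at alpha: (1) its per-larva
# restrictive-temperature mean speeds are lower than the control's, and
# (2) its per-larva normalized temperature-shift changes n = (r - p) / p are
# lower than the control's. No multiple-testing correction enters the
# verdict; Benjamini-Hochberg adjusted p-values are reported as an
# informational extra.

#' Normalized temperature-shift change
#'
#' `n = (r - p) / p` for one larva: the relative change in mean speed from
#' the permissive to the restrictive temperature. Vectorized. Larvae with a
#' non-positive permissive speed get `NA` with a warning; hit calling drops
#' them from the normalized-change criterion.
#'
#' @param r,p Mean speeds at restrictive and permissive temperature, um/sec.
#' @return Dimensionless relative change(s).
#' @export
#' @examples
#' normalized_change(98.7, 65.0) # ~0.518
normalized_change <- function(r, p) {
  bad <- !is.finite(p) | p <= 0
  if (any(bad)) {
    warn(sprintf(
      "%d larva(e) with non-positive permissive speed: normalized change undefined, dropped.",
      sum(bad)))
  }
  out <- (r - p) / p
  out[bad] <- NA_real_
  out
}

#' Fold change across the temperature shift
#'
#' Mean restrictive-temperature speed divided by mean permissive-temperature
#' speed. Equals `1 + mean normalized change` only in the noise-free limit;
#' per larva, `fold = n + 1` holds exactly.
#'
#' @param mean_r,mean_p Group mean speeds, um/sec.
#' @return Dimensionless ratio; `NA` with a warning when `mean_p <= 0`.
#' @export
#' @examples
#' fold_change(98.7, 65.0) # ~1.52, the control's "roughly 1.5-fold"
fold_change <- function(mean_r, mean_p) {
  bad <- !is.finite(mean_p) | mean_p <= 0
  if (any(bad)) {
    warn("Non-positive permissive mean speed: fold change undefined.")
  }
  out <- mean_r / mean_p
  out[bad] <- NA_real_
  out
}

#' One-tailed Welch two-sample t test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite degrees
#' of freedom, under the null of equal means, with a one-tailed alternative.
#' `alternative = "less"` tests whether the mean of `x` is below the mean of
#' `y`.
#'
#' @param x,y Numeric samples, each with at least two finite values.
#' @param alternative `"less"` or `"greater"` (for the mean of `x` relative
#'   to the mean of `y`).
#' @param label Optional label (e.g. a genotype) used in error messages.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6), "less")$p_value
welch_t_test <- function(x, y, alternative = c("less", "greater"),
                         label = NULL) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort(sprintf("Welch test needs >= 2 finite values per sample%s.",
                  if (is.null(label)) "" else paste0(" (", label, ")")),
          class = "larvatrack_stats_error")
  }
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  se2 <- vx + vy
  if (se2 == 0) {
    # identical constants: no evidence either way
    return(list(statistic = 0, df = length(x) + length(y) - 2, p_value = 0.5))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- if (alternative == "less") pt(tstat, df) else pt(tstat, df,
                                                        lower.tail = FALSE)
  list(statistic = tstat, df = df, p_value = p)
}

#' Classify one genotype against the control
#'
#' Applies the two-criterion slow definition. Criterion 1: per-larva
#' restrictive-temperature mean speeds, genotype lower than control,
#' one-tailed Welch test. Criterion 2: per-larva normalized changes
#' `n = (r - p) / p`, genotype lower than control, one-tailed Welch test.
#' `is_slow` requires both p-values below `alpha`.
#'
#' @param genotype_df,control_df Paired per-larva tibbles with columns
#'   `speed_permissive` and `speed_restrictive` (one row per larva).
#' @param genotype Label for the output row.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `genotype`, `n_larvae`, `mean_permissive`,
#'   `mean_restrictive`, `fold_change`, `norm_changes` (list column of
#'   per-larva n), `p_restrictive`, `p_normalized`, `is_slow`,
#'   `n_dropped_normalized`.
#' @export
classify_slow <- function(genotype_df, control_df, genotype = "genotype",
                          alpha = 0.05) {
  for (df in list(genotype_df, control_df)) {
    if (nrow(df) < 2) {
      abort(sprintf("Genotype `%s`: need >= 2 larvae with paired records.",
                    genotype),
            class = "larvatrack_stats_error")
    }
  }
  gr <- genotype_df$speed_restrictive
  cr <- control_df$speed_restrictive
  gn <- normalized_change(gr, genotype_df$speed_permissive)
  cn <- normalized_change(cr, control_df$speed_permissive)

  p1 <- welch_t_test(gr, cr, "less", label = genotype)$p_value
  p2 <- welch_t_test(gn, cn, "less", label = genotype)$p_value

  mean_p <- mean(genotype_df$speed_permissive)
  mean_r <- mean(gr)
  tibble::tibble(
    genotype = genotype,
    n_larvae = nrow(genotype_df),
    mean_permissive = mean_p,
    mean_restrictive = mean_r,
    fold_change = fold_change(mean_r, mean_p),
    norm_changes = list(gn),
    p_restrictive = p1,
    p_normalized = p2,
    is_slow = p1 < alpha && p2 < alpha,
    n_dropped_normalized = sum(!is.finite(gn))
  )
}

#' Run the full screen
#'
#' Classifies every experimental genotype against the control and assembles
#' the hit table, sorted by ascending fold change for reporting. The verdict
#' uses raw p-values (no multiple-testing correction); Benjamini-Hochberg
#' adjusted columns (`p_bh_restrictive`, `p_bh_normalized`) are attached for
#' reference.
#'
#' @param speeds Long tibble with columns `genotype`, `larva_id`,
#'   `temperature` (`"permissive"`/`"restrictive"`) and `mean_speed_um_s` —
#'   the `speeds` element of [simulate_screen()], [read_screen_speeds()]
#'   output, or rows assembled from [summarize_larva()].
#' @param control Genotype label of the control (default `"control"`).
#' @param alpha Significance level for both criteria.
#' @return A `screen_hits` tibble (one row per experimental genotype) with
#'   attributes `alpha`, `control` and `control_stats` (the control's own
#'   summary row). Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genotypes = 4,
#'                                          slow_genotype_indices = 1,
#'                                          slow_fold_change = 0.5,
#'                                          seed = 3))
#' run_screen(sim$speeds)
run_screen <- function(speeds, control = "control", alpha = 0.05) {
  need <- c("genotype", "larva_id", "temperature", "mean_speed_um_s")
  if (!all(need %in% names(speeds))) {
    abort(paste("`speeds` must have columns:", paste(need, collapse = ", ")),
          class = "larvatrack_input_error")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(speeds, dplyr::all_of(need)),
    names_from = "temperature", values_from = "mean_speed_um_s",
    names_prefix = "speed_"
  )
  if (!all(c("speed_permissive", "speed_restrictive") %in% names(wide)) ||
      anyNA(wide$speed_permissive) || anyNA(wide$speed_restrictive)) {
    abort("Every larva needs both a permissive and a restrictive record.",
          class = "larvatrack_input_error")
  }
  if (!control %in% wide$genotype) {
    abort(sprintf("Control genotype `%s` not found.", control),
          class = "larvatrack_input_error")
  }
  control_df <- wide[wide$genotype == control, , drop = FALSE]
  others <- setdiff(unique(wide$genotype), control)

  calls <- dplyr::bind_rows(lapply(others, function(g) {
    classify_slow(wide[wide$genotype == g, , drop = FALSE], control_df,
                  genotype = g, alpha = alpha)
  }))
  if (nrow(calls) > 0) {
    calls$p_bh_restrictive <- p.adjust(calls$p_restrictive, method = "BH")
    calls$p_bh_normalized <- p.adjust(calls$p_normalized, method = "BH")
    calls <- dplyr::arrange(calls, .data$fold_change)
  } else {
    calls <- tibble::tibble(
      genotype = character(), n_larvae = integer(),
      mean_permissive = numeric(), mean_restrictive = numeric(),
      fold_change = numeric(), norm_changes = list(),
      p_restrictive = numeric(), p_normalized = numeric(),
      is_slow = logical(), n_dropped_normalized = integer(),
      p_bh_restrictive = numeric(), p_bh_normalized = numeric()
    )
  }

  ctrl_n <- normalized_change(control_df$speed_restrictive,
                              control_df$speed_permissive)
  control_stats <- tibble::tibble(
    genotype = control,
    n_larvae = nrow(control_df),
    mean_permissive = mean(control_df$speed_permissive),
    mean_restrictive = mean(control_df$speed_restrictive),
    fold_change = fold_change(mean(control_df$speed_restrictive),
                              mean(control_df$speed_permissive)),
    norm_changes = list(ctrl_n)
  )
  structure(calls,
            class = c("screen_hits", class(tibble::tibble())),
            alpha = alpha, control = control, control_stats = control_stats)
}

#' @export
print.screen_hits <- function(x, ...) {
  cs <- attr(x, "control_stats")
  cat(sprintf(
    "<screen_hits> %d genotype(s) vs `%s` (fold %.2f), alpha = %g, %d slow\n",
    nrow(x), attr(x, "control"), cs$fold_change, attr(x, "alpha"),
    sum(x$is_slow)))
  NextMethod()
}

#' @describeIn run_screen Tidy the hit table (drops the list column).
#' @param x A `screen_hits` object.
#' @param ... Unused.
#' @export
tidy.screen_hits <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$norm_changes <- NULL
  attr(out, "alpha") <- NULL
  attr(out, "control") <- NULL
  attr(out, "control_stats") <- NULL
  out
}

#' @describeIn run_screen One-row screen summary.
#' @export
glance.screen_hits <- function(x, ...) {
  cs <- attr(x, "control_stats")
  tibble::tibble(
    n_genotypes = nrow(x),
    n_slow = sum(x$is_slow),
    alpha = attr(x, "alpha"),
    control_mean_permissive = cs$mean_permissive,
    control_mean_restrictive = cs$mean_restrictive,
    control_fold_change = cs$fold_change
  )
}

#' Write hit calls as CSV
#'
#' @param hits A `screen_hits` table.
#' @param path CSV file path.
#' @export
write_hit_calls <- function(hits, path) {
  write.csv(as.data.frame(tidy(hits)), path, row.names = FALSE)
  invisible(path)
}
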