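# Screen-level generator: paired per-larva mean speeds at the permissive and
# restrictive temperatures for a control genotype plus experimental
# genotypes, with planted "slow" genotypes whose temperature-shift fold
# change is reduced. Ground-truth labels ride along so hit-calling can be
# scored against a known answer.

#' Simulate a paired-temperature behavioral screen
#'
#' Each larva receives a permissive-temperature mean speed drawn from the
#' configured noise model and a restrictive-temperature speed equal to
#' `permissive x genotype fold change x multiplicative noise` (a mean-one
#' lognormal factor with SD `restrictive_noise_sd`). Control and non-slow
#' genotypes use `control_fold_change`; genotypes listed in
#' `slow_genotype_indices` use `slow_fold_change`.
#'
#' With the default `"lognormal"` noise model the permissive draw has exactly
#' the configured mean and SD. The `"normal-truncated-at-zero"` model
#' rejection-samples a normal with those parameters; truncation pulls the
#' realized mean above and the SD below the nominal values, which matters
#' when the coefficient of variation is large.
#'
#' @param cfg A [screen_sim_config()].
#'
#' @return A `screen_sim` list: `speeds`, a tibble in long format
#'   (`genotype`, `larva_id`, `recording_id`, `temperature_C`, `temperature`,
#'   `mean_speed_um_s`) with the control labeled `"control"`; and `truth`, a
#'   tibble (`genotype`, `fold_change_true`, `is_slow_true`). Deterministic
#'   for a fixed seed.
#' @export
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genotypes = 3,
#'                                          slow_genotype_indices = 2,
#'                                          slow_fold_change = 0.8,
#'                                          seed = 42))
#' dplyr::count(sim$speeds, genotype)
simulate_screen <- function(cfg = screen_sim_config()) {
  cfg <- validate_screen_sim_config(cfg)
  set.seed(cfg$seed)
  labels <- c("control",
              sprintf("G%03d", seq_len(cfg$n_genotypes)))
  n_per <- c(cfg$n_control_larvae,
             rep(cfg$n_larvae_per_genotype, cfg$n_genotypes))
  slow <- c(FALSE, seq_len(cfg$n_genotypes) %in% cfg$slow_genotype_indices)
  folds <- ifelse(slow, cfg$slow_fold_change, cfg$control_fold_change)

  rows <- purrr::pmap(
    list(labels, n_per, folds),
    function(lab, n, fold) {
      p <- draw_speeds(n, cfg$control_permissive_mean,
                       cfg$control_permissive_sd, cfg$speed_noise_model)
      m <- if (cfg$restrictive_noise_sd > 0) {
        rlnorm_mean_sd(n, 1, cfg$restrictive_noise_sd)
      } else {
        rep(1, n)
      }
      r <- p * fold * m
      tibble::tibble(
        genotype = lab,
        larva_id = rep(sprintf("%s_L%02d", lab, seq_len(n)), 2),
        recording_id = 1L,
        temperature_C = rep(c(23, 28), each = n),
        temperature = rep(c("permissive", "restrictive"), each = n),
        mean_speed_um_s = c(p, r)
      )
    }
  )

  list(
    speeds = dplyr::bind_rows(rows),
    truth = tibble::tibble(genotype = labels, fold_change_true = folds,
                           is_slow_true = slow)
  )
}

draw_speeds <- function(n, mean, sd, model) {
  if (n == 0) return(numeric())
  if (sd == 0) return(rep(mean, n))
  if (model == "lognormal") {
    rlnorm_mean_sd(n, mean, sd)
  } else {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
}

# lognormal parameterized by its own mean and SD
rlnorm_mean_sd <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  rlnorm(n, meanlog, sdlog)
}

#' Write a simulated screen's speed table as CSV
#'
#' Columns: `genotype`, `larva_id`, `recording_id`, `temperature_C`,
#' `mean_speed_um_s`. Readable back with [read_screen_speeds()], which
#' restores the `temperature` factor from `temperature_C` (23 = permissive,
#' 28 = restrictive by assay convention; any cooler/warmer pair works).
#'
#' @param speeds A speeds tibble (from [simulate_screen()] or assembled from
#'   [summarize_larva()] output).
#' @param path CSV file path.
#' @export
write_screen_speeds <- function(speeds, path) {
  keep <- intersect(
    c("genotype", "larva_id", "recording_id", "temperature_C",
      "mean_speed_um_s"),
    names(speeds)
  )
  write.csv(as.data.frame(speeds[keep]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_speeds
#' @export
read_screen_speeds <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  if (!"temperature" %in% names(df)) {
    temps <- sort(unique(df$temperature_C))
    if (length(temps) != 2) {
      abort("Expected exactly two recording temperatures in the speeds CSV.")
    }
    df$temperature <- ifelse(df$temperature_C == temps[1],
                             "permissive", "restrictive")
  }
  df
}
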