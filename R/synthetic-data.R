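#' Configuration of a synthetic culture cohort
#'
#' Defaults emulate the study conditions: 72-hour CD34+ liquid cultures
#' seeded at 0.75e5 cells/mL; three healthy donors per condition with daily
#' fold-change growth rates 1.54 +/- 0.09 without CXCL8 and 1.17 +/- 0.13
#' with CXCL8 (the +/- values are treated as the SD across donors); 19 CMML
#' samples whose relative fitness is drawn uniformly from \[1.08, 1.67\].
#' Counts carry multiplicative lognormal noise parameterised by its
#' coefficient of variation.
#'
#' @param n_healthy healthy samples per condition (>= 1).
#' @param n_cmml CMML samples.
#' @param healthy_mean_no_cxcl8,healthy_sd_no_cxcl8 daily fold-change
#'   distribution of healthy growth without CXCL8.
#' @param healthy_mean_cxcl8,healthy_sd_cxcl8 same, with 10 ng/mL CXCL8.
#' @param cmml_fitness_low,cmml_fitness_high uniform band of CMML relative
#'   fitness (dimensionless, `low <= high`).
#' @param seed_density seeding density, cells/mL.
#' @param timepoints hours, strictly ascending, first = 0.
#' @param noise_cv coefficient of variation of the lognormal count noise
#'   (>= 0).
#' @param rng_seed integer seed; the whole cohort is deterministic given it.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_healthy = 3, n_cmml = 19,
                          healthy_mean_no_cxcl8 = 1.54,
                          healthy_sd_no_cxcl8 = 0.09,
                          healthy_mean_cxcl8 = 1.17,
                          healthy_sd_cxcl8 = 0.13,
                          cmml_fitness_low = 1.08,
                          cmml_fitness_high = 1.67,
                          seed_density = 0.75e5,
                          timepoints = c(0, 72),
                          noise_cv = 0.1,
                          rng_seed = 1L) {
  check_scalar_pos(healthy_mean_no_cxcl8, "healthy_mean_no_cxcl8")
  check_scalar_pos(healthy_mean_cxcl8, "healthy_mean_cxcl8")
  check_scalar_pos(seed_density, "seed_density")
  if (healthy_sd_no_cxcl8 < 0 || healthy_sd_cxcl8 < 0)
    stop_invalid("healthy-rate SDs must be >= 0")
  if (noise_cv < 0) stop_invalid("`noise_cv` must be >= 0")
  if (cmml_fitness_low > cmml_fitness_high)
    stop_invalid("`cmml_fitness_low` must be <= `cmml_fitness_high`")
  if (cmml_fitness_low <= 0)
    stop_invalid("fitness band must be positive")
  if (n_healthy < 1)
    stop_invalid("`n_healthy` must be >= 1 (fitness needs a healthy denominator)")
  if (n_cmml < 0) stop_invalid("`n_cmml` must be >= 0")
  check_timepoints(timepoints)
  structure(
    list(n_healthy = as.integer(n_healthy), n_cmml = as.integer(n_cmml),
         healthy_mean_no_cxcl8 = healthy_mean_no_cxcl8,
         healthy_sd_no_cxcl8 = healthy_sd_no_cxcl8,
         healthy_mean_cxcl8 = healthy_mean_cxcl8,
         healthy_sd_cxcl8 = healthy_sd_cxcl8,
         cmml_fitness_low = cmml_fitness_low,
         cmml_fitness_high = cmml_fitness_high,
         seed_density = seed_density,
         timepoints = as.numeric(timepoints),
         noise_cv = noise_cv,
         rng_seed = as.integer(rng_seed)),
    class = "cohort_config"
  )
}

# Lognormal factors with mean 1 and coefficient of variation cv.
.lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one noisy culture-count series
#'
#' The noise-free trajectory follows the exponential growth law
#' `C(t) = seed_density * growth_rate^(t / 24)` (daily fold-change
#' convention). Each count after seeding is multiplied by an independent
#' lognormal factor with unit mean and coefficient of variation `noise_cv`;
#' the count at time 0 is the seeding density exactly.
#'
#' @param growth_rate daily fold-change (> 0).
#' @param seed_density cells/mL at seeding (> 0).
#' @param timepoints hours, ascending from 0.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param rng_seed optional seed for reproducibility.
#' @param sample_id,group,condition labels for the resulting series.
#' @return A [count_series()].
#' @examples
#' generate_count_series(2, 0.75e5, c(0, 72), noise_cv = 0)$counts # 6e5 at 72 h
#' @export
generate_count_series <- function(growth_rate, seed_density = 0.75e5,
                                  timepoints = c(0, 72), noise_cv = 0,
                                  rng_seed = NULL, sample_id = "synthetic",
                                  group = "healthy", condition = "control") {
  check_scalar_pos(growth_rate, "growth_rate")
  check_scalar_pos(seed_density, "seed_density")
  check_timepoints(timepoints)
  if (noise_cv < 0) stop_invalid("`noise_cv` must be >= 0")
  counts <- with_seed(rng_seed, {
    ideal <- seed_density * growth_rate^(timepoints / 24)
    noise <- c(1, .lognormal_noise(length(timepoints) - 1L, noise_cv))
    ideal * noise
  })
  count_series(sample_id, group, condition, timepoints, counts)
}

# Draw from N(mean, sd) truncated at 0 by rejection (negligible mass below 0
# for the defaults; guarded anyway so no negative rate can ever escape).
.rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic cohort of culture-count series
#'
#' Draws healthy growth rates from condition-specific normal distributions
#' truncated at 0, and gives each CMML sample a single relative fitness drawn
#' uniformly from the configured band; the CMML rate under each condition is
#' that fitness times the realised mean of the healthy rates drawn for the
#' condition, so the generating fitness is exactly what a downstream
#' fitness analysis should recover. Counts are produced with
#' [generate_count_series()] under the configured noise. A truth table of
#' generating rates and fitnesses accompanies the data for recovery tests.
#'
#' @param config a [cohort_config()].
#' @return A list of class `synthetic_cohort`: `series` (list of
#'   [count_series()], one per sample x condition), `truth` (data frame
#'   `sample_id`, `group`, `condition`, `true_rate`, `true_fitness`) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$rng_seed, {
    conds <- c(control = "control", cxcl8 = "cxcl8")
    h_mean <- c(control = config$healthy_mean_no_cxcl8,
                cxcl8 = config$healthy_mean_cxcl8)
    h_sd <- c(control = config$healthy_sd_no_cxcl8,
              cxcl8 = config$healthy_sd_cxcl8)
    healthy_rates <- lapply(conds, function(cc)
      .rnorm_trunc0(config$n_healthy, h_mean[[cc]], h_sd[[cc]]))
    fitness <- if (config$n_cmml > 0)
      runif(config$n_cmml, config$cmml_fitness_low, config$cmml_fitness_high)
    else numeric(0)

    series <- list(); truth <- list()
    for (cc in conds) {
      hm <- mean(healthy_rates[[cc]])
      for (i in seq_len(config$n_healthy)) {
        id <- sprintf("healthy_%02d", i)
        rate <- healthy_rates[[cc]][i]
        series[[length(series) + 1L]] <- generate_count_series(
          rate, config$seed_density, config$timepoints, config$noise_cv,
          rng_seed = NULL, sample_id = id, group = "healthy", condition = cc)
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = id, group = "healthy", condition = cc,
          true_rate = rate, true_fitness = rate / hm,
          stringsAsFactors = FALSE)
      }
      for (j in seq_len(config$n_cmml)) {
        id <- sprintf("cmml_%02d", j)
        rate <- fitness[j] * hm
        series[[length(series) + 1L]] <- generate_count_series(
          rate, config$seed_density, config$timepoints, config$noise_cv,
          rng_seed = NULL, sample_id = id, group = "cmml", condition = cc)
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = id, group = "cmml", condition = cc,
          true_rate = rate, true_fitness = fitness[j],
          stringsAsFactors = FALSE)
      }
    }
    structure(
      list(series = series, truth = do.call(rbind, truth), config = config),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d series (%d healthy + %d CMML per condition), seed %d\n",
    length(x$series), x$config$n_healthy, x$config$n_cmml,
    x$config$rng_seed))
  invisible(x)
}
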