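#' Pipeline configuration
#'
#' Builds and validates the configuration of [run_pipeline()]. Either a
#' `counts_file` (CSV in the [read_counts_table()] schema) or a synthetic
#' cohort (the default) feeds the pipeline. Unknown keys are rejected so a
#' typo in a parameter name cannot silently fall back to a default.
#'
#' @param counts_file optional path to a counts CSV; when `NULL` a synthetic
#'   cohort is generated from `cohort`.
#' @param cohort a [cohort_config()] (used when `counts_file` is `NULL`).
#' @param rate_method,rate_convention passed to [estimate_growth_rate()].
#' @param N,division_rate,initial_mutants Moran-compartment parameters.
#' @param method fixation-time method: `"analytic"`, `"exact"` or `"mc"`.
#' @param replicates Monte-Carlo replicates when `method = "mc"`.
#' @param sensitivity_r,sensitivity_N,sensitivity_division_rates grid axes
#'   for [sensitivity_grid()].
#' @param rng_seed integer master seed for all stochastic stages.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts_file = NULL,
                            cohort = cohort_config(),
                            rate_method = "two_point",
                            rate_convention = "daily_fold",
                            N = 100000, division_rate = 1,
                            initial_mutants = 1,
                            method = "analytic",
                            replicates = 10000,
                            sensitivity_r = seq(1.05, 2, by = 0.05),
                            sensitivity_N = unname(moran_N_bounds()),
                            sensitivity_division_rates = 1,
                            rng_seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  if (!method %in% c("analytic", "exact", "mc"))
    stop_invalid("unknown fixation method '%s'", method)
  structure(
    list(counts_file = counts_file, cohort = cohort,
         rate_method = rate_method, rate_convention = rate_convention,
         N = N, division_rate = division_rate,
         initial_mutants = initial_mutants, method = method,
         replicates = replicates, sensitivity_r = sensitivity_r,
         sensitivity_N = sensitivity_N,
         sensitivity_division_rates = sensitivity_division_rates,
         rng_seed = as.integer(rng_seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `cohort`
#' key holds a nested mapping with [cohort_config()] arguments. Unknown keys
#' at either level are an error.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- setdiff(names(formals(pipeline_config)), "cohort")
  unknown <- setdiff(names(raw), c(known_top, "cohort"))
  if (length(unknown))
    stop_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cohort_args <- raw$cohort %||% list()
  unknown_c <- setdiff(names(cohort_args), names(formals(cohort_config)))
  if (length(unknown_c))
    stop_invalid("unknown cohort key(s): %s", paste(unknown_c, collapse = ", "))
  raw$cohort <- NULL
  args <- c(raw, list(cohort = do.call(cohort_config, cohort_args)))
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Counts (synthetic or from file) -> per-sample growth rates -> healthy
#' summaries -> fitness table with advantageous-subset report -> per-sample
#' fixation scenarios (with vs. without CXCL8) -> sensitivity grid. All
#' tables are written as CSV into `out_dir` together with a JSON manifest
#' recording seeds, configuration and file digests.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory tables: `rates`, `summaries`,
#'   `fitness`, `scenarios`, `sensitivity`, `manifest` (plus `truth` for a
#'   synthetic run).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = ".") {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  files <- character(0)

  # stage 1: counts
  truth <- NULL
  if (is.null(config$counts_file)) {
    cohort <- generate_cohort(config$cohort)
    series <- cohort$series
    truth <- cohort$truth
    write_counts_table(series, path("counts.csv"))
    write_truth_table(cohort, path("truth.csv"))
    files <- c(files, path("counts.csv"), path("truth.csv"))
  } else {
    series <- read_counts_table(config$counts_file)
  }

  # stage 2: growth rates
  rates <- lapply(series, estimate_growth_rate,
                  method = config$rate_method,
                  convention = config$rate_convention)
  rates_df <- do.call(rbind, lapply(rates, function(g) data.frame(
    sample_id = g$sample_id, group = g$group, condition = g$condition,
    rate = g$rate, stringsAsFactors = FALSE)))
  write.csv(rates_df, path("rates.csv"), row.names = FALSE, quote = FALSE)
  files <- c(files, path("rates.csv"))

  # stage 3: healthy summaries + fitness
  conds <- unique(rates_df$condition)
  summaries <- setNames(
    lapply(conds, function(cc) summarize_healthy(rates, cc)), conds)
  summary_df <- do.call(rbind, lapply(summaries, function(s) data.frame(
    condition = s$condition, n = s$n, mean_rate = s$mean_rate,
    sd_rate = s$sd_rate, min_rate = s$min_rate, max_rate = s$max_rate,
    stringsAsFactors = FALSE)))
  write.csv(summary_df, path("healthy_summary.csv"), row.names = FALSE,
            quote = FALSE)
  fit <- fitness_table(rates, summaries)
  fit_out <- as.data.frame(fit)
  write.csv(fit_out, path("fitness.csv"), row.names = FALSE, quote = FALSE)
  files <- c(files, path("healthy_summary.csv"), path("fitness.csv"))

  # stage 4: per-sample fixation scenarios (CMML only, needs both conditions)
  params <- moran_parameters(N = config$N, r = 2,
                             division_rate = config$division_rate,
                             initial_mutants = config$initial_mutants)
  scenarios <- NULL
  if (all(c("control", "cxcl8") %in% conds)) {
    cm_ctrl <- rates_df[rates_df$group == "cmml" &
                          rates_df$condition == "control", ]
    cm_cx <- rates_df[rates_df$group == "cmml" &
                        rates_df$condition == "cxcl8", ]
    rate_cx <- setNames(cm_cx$rate, cm_cx$sample_id)
    rows <- lapply(seq_len(nrow(cm_ctrl)), function(i) {
      id <- cm_ctrl$sample_id[i]
      g_with <- if (id %in% names(rate_cx)) rate_cx[[id]] else cm_ctrl$rate[i]
      fixation_for_sample(cm_ctrl$rate[i],
                          healthy_without = summaries[["control"]],
                          healthy_with = summaries[["cxcl8"]],
                          params_template = params,
                          method = config$method,
                          sample_id = id,
                          replicates = config$replicates,
                          rng_seed = config$rng_seed + i,
                          g_cmml_with = g_with)
    })
    if (length(rows)) {
      scenarios <- do.call(rbind, rows)
      write.csv(scenarios, path("scenarios.csv"), row.names = FALSE,
                quote = FALSE)
      files <- c(files, path("scenarios.csv"))
    }
  }

  # stage 5: sensitivity grid
  grid <- sensitivity_grid(r_values = config$sensitivity_r,
                           N_values = config$sensitivity_N,
                           division_rates = config$sensitivity_division_rates)
  write.csv(as.data.frame(grid), path("sensitivity.csv"), row.names = FALSE,
            quote = FALSE)
  files <- c(files, path("sensitivity.csv"))

  manifest <- write_manifest(
    path("manifest.json"), command = "pipeline",
    config = list(pipeline = unclass(config),
                  cohort = unclass(config$cohort)),
    seeds = list(rng_seed = config$rng_seed,
                 cohort_seed = config$cohort$rng_seed),
    files = files)

  invisible(list(rates = rates_df, summaries = summaries, fitness = fit,
                 scenarios = scenarios, sensitivity = grid, truth = truth,
                 manifest = manifest))
}
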