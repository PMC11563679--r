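#' Closed-form approximation of the conditional fixation time
#'
#' Large-N approximation of the expected number of Moran iterations for a
#' single advantageous founder (`initial_mutants = 1`, \eqn{r > 1}) to take over
#' the compartment, conditioned on takeover:
#'
#' \deqn{T(r, N) = N \ln(N) \frac{r + 1}{r - 1} \textrm{ iterations,}}
#'
#' the deterministic logistic-sweep limit of the selection process. Its
#' accuracy against the exact solver is quantified by
#' [approximation_quality_report()]; the approximation targets the *conditional*
#' fixation time (see the methods vignette).
#'
#' @param params a [moran_parameters()] object with \eqn{r > 1} and
#'   `initial_mutants = 1`.
#' @return Expected iterations to fixation.
#' @examples
#' approximate_fixation_time(moran_parameters(N = 100000, r = 1.67))
#' @export
approximate_fixation_time <- function(params) {
  stopifnot(inherits(params, "moran_params"))
  if (params$r <= 1)
    stop_invalid(paste0(
      "the fixation-time approximation requires r > 1 ",
      "(an advantageous mutant); got r = %g"), params$r)
  if (params$initial_mutants != 1)
    stop_invalid("the approximation is for a single founder (initial_mutants = 1)")
  N <- params$N; r <- params$r
  N * log(N) * (r + 1) / (r - 1)
}

#' Convert Moran iterations to calendar years
#'
#' The compartment turns over in `1/division_rate` years, so one iteration
#' takes `1 / (division_rate * N)` years.
#'
#' @param iterations iteration count(s), >= 0.
#' @param params a [moran_parameters()] object supplying `N` and
#'   `division_rate`.
#' @return Years, same length as `iterations`.
#' @export
iterations_to_years <- function(iterations, params) {
  stopifnot(inherits(params, "moran_params"))
  if (any(iterations < 0, na.rm = TRUE))
    stop_invalid("`iterations` must be >= 0")
  iterations / (params$division_rate * params$N)
}

# Dispatch a fixation time (iterations) for one r under a method tag.
.fixation_iterations <- function(r, params_template, method, replicates,
                                 rng_seed) {
  p <- moran_parameters(N = params_template$N, r = r,
                        division_rate = params_template$division_rate,
                        initial_mutants = params_template$initial_mutants)
  switch(method,
    analytic = approximate_fixation_time(p),
    exact = exact_conditional_fixation_time(p),
    mc = simulate_fixation(p, replicates, rng_seed)$mean_conditional_iterations,
    stop_invalid("unknown method '%s' (use analytic, exact or mc)", method))
}

#' Per-sample fixation scenario with and without CXCL8
#'
#' For one CMML sample's growth rate, computes its relative fitness against
#' the healthy cohort mean under each condition (control medium vs. CXCL8,
#' which suppresses healthy but not CMML growth), then the predicted takeover
#' time of the stem-cell compartment under each fitness. Branches with
#' \eqn{r \le 1} carry no takeover prediction: the mutant is not advantageous and
#' the fixation formula does not apply; they are reported as the sentinel
#' `NA` with `note = "no takeover predicted"`.
#'
#' @param g_cmml the sample's growth rate (per day, same convention as the
#'   healthy summaries) measured without CXCL8.
#' @param g_cmml_with the sample's growth rate measured with CXCL8; defaults
#'   to `g_cmml`, since CXCL8 leaves CMML growth unchanged while suppressing
#'   the healthy cells in the denominator.
#' @param healthy_without,healthy_with [summarize_healthy()] summaries for
#'   the control and CXCL8 conditions.
#' @param params_template a [moran_parameters()] object providing `N`,
#'   `division_rate` and `initial_mutants`; its `r` is ignored.
#' @param method one of `"analytic"` (default, any `N`), `"exact"`
#'   (`N <= 2000`) or `"mc"`.
#' @param sample_id label carried into the result.
#' @param replicates,rng_seed Monte-Carlo controls, used when
#'   `method = "mc"`.
#' @return A one-row data frame of class `scenario_result` with columns
#'   `sample_id`, `r_without_cxcl8`, `r_with_cxcl8`,
#'   `fixation_years_without`, `fixation_years_with`, `speedup_factor`
#'   (= without / with), `method`, `note`.
#' @export
fixation_for_sample <- function(g_cmml, healthy_without, healthy_with,
                                params_template = moran_parameters(),
                                method = c("analytic", "exact", "mc"),
                                sample_id = NA_character_,
                                replicates = 10000, rng_seed = NULL,
                                g_cmml_with = g_cmml) {
  method <- match.arg(method)
  stopifnot(inherits(healthy_without, "healthy_summary"),
            inherits(healthy_with, "healthy_summary"))
  if (healthy_without$condition != "control" ||
      healthy_with$condition != "cxcl8")
    stop_invalid("summaries must be for conditions 'control' and 'cxcl8'")
  check_scalar_pos(g_cmml, "g_cmml")
  check_scalar_pos(g_cmml_with, "g_cmml_with")
  r_without <- g_cmml / healthy_without$mean_rate
  r_with <- g_cmml_with / healthy_with$mean_rate
  time_of <- function(r) {
    if (r <= 1) return(NA_real_)
    it <- .fixation_iterations(r, params_template, method, replicates, rng_seed)
    iterations_to_years(it, params_template)
  }
  y_without <- time_of(r_without)
  y_with <- time_of(r_with)
  note <- if (is.na(y_without) || is.na(y_with))
    "no takeover predicted" else ""
  out <- data.frame(
    sample_id = sample_id,
    r_without_cxcl8 = r_without,
    r_with_cxcl8 = r_with,
    fixation_years_without = y_without,
    fixation_years_with = y_with,
    speedup_factor = y_without / y_with,
    method = method,
    note = note,
    stringsAsFactors = FALSE
  )
  class(out) <- c("scenario_result", class(out))
  out
}

#' Sensitivity of fixation time to fitness, compartment size and division rate
#'
#' Evaluates the fixation time (in years) over a grid of relative fitness
#' values, compartment sizes and division rates, and the local sensitivity
#' `|dT/dr|` by central finite differences along the fitness axis for each
#' `(N, division_rate)` combination. The row of maximal sensitivity is
#' flagged; with the default grid the maximum sits at the low-fitness end,
#' where takeover times react most strongly to small fitness changes.
#'
#' @param r_values strictly ascending fitness grid, all > 1. Default 21
#'   points over (1, 2].
#' @param N_values compartment sizes; default the literature bounds
#'   `c(25000, 100000, 1300000)`.
#' @param division_rates divisions per cell per year; default `1`.
#' @param method `"analytic"` (default) or `"exact"` (small `N` only).
#' @return A `sensitivity_grid` data frame with columns `r`, `N`,
#'   `division_rate`, `fixation_years`, `dT_dr_abs` (NA at grid edges) and
#'   `max_sensitivity` (logical flag per `(N, division_rate)` block).
#' @export
sensitivity_grid <- function(r_values = seq(1.05, 2, by = 0.05),
                             N_values = unname(moran_N_bounds()),
                             division_rates = 1,
                             method = c("analytic", "exact")) {
  method <- match.arg(method)
  if (any(r_values <= 1)) stop_invalid("all `r_values` must be > 1")
  if (any(diff(r_values) <= 0))
    stop_invalid("`r_values` must be strictly ascending")
  N_values <- sort(N_values)
  division_rates <- sort(division_rates)
  if (length(r_values) < 2)
    warning("single-point fitness axis: sensitivity undefined")
  grid <- expand.grid(r = r_values, N = N_values,
                      division_rate = division_rates,
                      KEEP.OUT.ATTRS = FALSE)
  grid$fixation_years <- mapply(function(r, N, d) {
    p <- moran_parameters(N = N, r = r, division_rate = d)
    it <- switch(method,
                 analytic = approximate_fixation_time(p),
                 exact = exact_conditional_fixation_time(p))
    iterations_to_years(it, p)
  }, grid$r, grid$N, grid$division_rate)
  grid$dT_dr_abs <- NA_real_
  grid$max_sensitivity <- FALSE
  for (blk in split(seq_len(nrow(grid)),
                    list(grid$N, grid$division_rate), drop = TRUE)) {
    if (length(blk) < 3) next
    y <- grid$fixation_years[blk]
    r <- grid$r[blk]
    inner <- 2:(length(blk) - 1)
    grid$dT_dr_abs[blk[inner]] <-
      abs((y[inner + 1] - y[inner - 1]) / (r[inner + 1] - r[inner - 1]))
    imax <- blk[inner][which.max(grid$dT_dr_abs[blk[inner]])]
    grid$max_sensitivity[imax] <- TRUE
  }
  class(grid) <- c("sensitivity_grid", class(grid))
  grid
}

#' Approximation-quality report for the closed-form fixation time
#'
#' Compares the closed-form fixation-time approximation against the exact
#' conditional solver over a grid of `(N, r)` and records the signed relative
#' deviation `(approx - exact) / exact`. The deviation varies smoothly in
#' both axes (no sign-flipping noise), which is the check that the formula
#' and the chain describe the same quantity.
#'
#' @param N_values compartment sizes (exact solver applies; keep `<= 2000`).
#' @param r_values fitness values, all > 1.
#' @return Data frame with `N`, `r`, `approx_iterations`,
#'   `exact_iterations`, `rel_deviation`.
#' @export
approximation_quality_report <- function(N_values = c(50, 100, 200, 350, 500),
                               r_values = c(1.1, 1.25, 1.5, 1.75, 2)) {
  if (any(r_values <= 1)) stop_invalid("all `r_values` must be > 1")
  grid <- expand.grid(N = N_values, r = r_values, KEEP.OUT.ATTRS = FALSE)
  grid$approx_iterations <- mapply(function(N, r)
    approximate_fixation_time(moran_parameters(N = N, r = r)),
    grid$N, grid$r)
  grid$exact_iterations <- mapply(function(N, r)
    exact_conditional_fixation_time(moran_parameters(N = N, r = r)),
    grid$N, grid$r)
  grid$rel_deviation <-
    (grid$approx_iterations - grid$exact_iterations) / grid$exact_iterations
  grid
}
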