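#' Simulate one trajectory of the mutant-count chain
#'
#' Runs the birth-death reduction of the Moran process from `initial_mutants`
#' to absorption at 0 (loss) or `N` (fixation). Every Moran iteration counts,
#' including self-replacement events in which the chain stays put; waiting
#' times in a state are drawn as a single geometric variate, which leaves the
#' distribution of the total iteration count unchanged.
#'
#' @param params a [moran_parameters()] object.
#' @param rng_seed optional integer seed; when given the trajectory is
#'   reproducible and the caller's RNG stream is left untouched.
#' @return A list with `absorbed_at` (0 or `N`) and `iterations`.
#' @export
simulate_trajectory <- function(params, rng_seed = NULL) {
  stopifnot(inherits(params, "moran_params"))
  res <- with_seed(rng_seed,
    cpp_simulate_kchain(params$N, params$r, params$initial_mutants, 1L))
  list(absorbed_at = res$absorbed[1], iterations = res$iterations[1])
}

#' Monte-Carlo estimate of fixation probability and conditional time
#'
#' Replicates the mutant-count chain and summarises the fraction of runs
#' absorbed at `N` and the mean iteration count among fixing runs, with
#' standard errors for both.
#'
#' @param params a [moran_parameters()] object.
#' @param replicates number of independent runs (>= 1).
#' @param rng_seed optional integer seed for reproducibility.
#' @return A `fixation_estimate` list: `method = "monte_carlo"`,
#'   `fixation_probability`, `prob_se`, `mean_conditional_iterations`,
#'   `standard_error` (of the conditional mean), `n_fixed`, `replicates`,
#'   `rng_seed`, and the `params` used. When no run fixes the conditional
#'   time is `NA` with a warning.
#' @examples
#' simulate_fixation(moran_parameters(N = 10, r = 2), 2000, rng_seed = 1)
#' @export
simulate_fixation <- function(params, replicates, rng_seed = NULL) {
  stopifnot(inherits(params, "moran_params"))
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1)
    stop_invalid("`replicates` must be >= 1")
  replicates <- as.integer(replicates)
  res <- with_seed(rng_seed,
    cpp_simulate_kchain(params$N, params$r, params$initial_mutants,
                        replicates))
  fixed <- res$absorbed == params$N
  p_hat <- mean(fixed)
  n_fix <- sum(fixed)
  if (n_fix == 0) {
    warning("no replicate reached fixation; conditional time undefined")
    t_hat <- NA_real_; t_se <- NA_real_
  } else {
    tt <- res$iterations[fixed]
    t_hat <- mean(tt)
    t_se <- if (n_fix > 1) sd(tt) / sqrt(n_fix) else NA_real_
  }
  structure(
    list(method = "monte_carlo",
         fixation_probability = p_hat,
         prob_se = sqrt(p_hat * (1 - p_hat) / replicates),
         mean_conditional_iterations = t_hat,
         standard_error = t_se,
         n_fixed = n_fix,
         replicates = replicates,
         rng_seed = rng_seed,
         params = params),
    class = "fixation_estimate"
  )
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("Fixation estimate (%s): P(fix) = %.4g", x$method,
              x$fixation_probability))
  if (!is.null(x$prob_se)) cat(sprintf(" (SE %.2g)", x$prob_se))
  cat(sprintf("\n  conditional iterations = %.6g", x$mean_conditional_iterations))
  if (!is.null(x$standard_error) && is.finite(x$standard_error))
    cat(sprintf(" (SE %.3g)", x$standard_error))
  cat("\n")
  invisible(x)
}

#' Agent-based Moran simulation (test oracle)
#'
#' Literal `N`-cell implementation: an explicit per-cell fitness vector, the
#' divider sampled with probability proportional to fitness, the dier sampled
#' uniformly and replaced by a copy of the divider. Distributionally identical
#' to [simulate_trajectory()]; kept as an independent oracle for small `N`
#' and never used in production runs.
#'
#' @inheritParams simulate_fixation
#' @param max_N guard; the agentwise path is O(N) per iteration and refuses
#'   compartments above this size (default 64).
#' @return As [simulate_fixation()], with `method = "agentwise"`.
#' @export
simulate_agentwise <- function(params, replicates, rng_seed = NULL,
                               max_N = 64) {
  stopifnot(inherits(params, "moran_params"))
  if (params$N > max_N)
    stop_invalid("agentwise simulation is a small-N oracle (N <= %d); got N = %d",
                 max_N, params$N)
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1)
    stop_invalid("`replicates` must be >= 1")
  replicates <- as.integer(replicates)
  res <- with_seed(rng_seed,
    cpp_simulate_agentwise(params$N, params$r, params$initial_mutants,
                           replicates))
  fixed <- res$absorbed == params$N
  p_hat <- mean(fixed)
  n_fix <- sum(fixed)
  tt <- res$iterations[fixed]
  structure(
    list(method = "agentwise",
         fixation_probability = p_hat,
         prob_se = sqrt(p_hat * (1 - p_hat) / replicates),
         mean_conditional_iterations = if (n_fix) mean(tt) else NA_real_,
         standard_error = if (n_fix > 1) sd(tt) / sqrt(n_fix) else NA_real_,
         n_fixed = n_fix,
         replicates = replicates,
         rng_seed = rng_seed,
         params = params),
    class = "fixation_estimate"
  )
}
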