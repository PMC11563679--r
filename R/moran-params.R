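#' Parameters of the two-type Moran process
#'
#' Bundles the compartment size `N`, the mutant's relative fitness `r`, the
#' per-cell division rate and the initial number of mutant cells. The baseline
#' parameterisation of the hematopoietic stem-cell compartment is
#' `N = 100000` active cells dividing once per year, with one mutant founder;
#' published estimates bound the compartment between 25,000 and 1.3 million
#' cells, exposed here as `moran_N_bounds()`.
#'
#' @param N integer compartment size, at least 2.
#' @param r relative fitness of the mutant lineage (> 0); healthy cells have
#'   fitness 1.
#' @param division_rate divisions per cell per year (> 0). The compartment
#'   turns over in `1/division_rate`, so one Moran iteration corresponds to
#'   `1/(division_rate * N)` years.
#' @param initial_mutants integer in `[1, N - 1]`; default a single founder.
#' @return An object of class `moran_params`.
#' @examples
#' p <- moran_parameters(N = 1000, r = 1.5)
#' step_probabilities(p, k = 1)
#' @export
moran_parameters <- function(N = 100000, r = 1, division_rate = 1,
                             initial_mutants = 1) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N < 2 ||
      N != round(N))
    stop_invalid("`N` must be a single integer >= 2")
  check_scalar_pos(r, "r")
  check_scalar_pos(division_rate, "division_rate")
  if (!is.numeric(initial_mutants) || length(initial_mutants) != 1L ||
      initial_mutants != round(initial_mutants) ||
      initial_mutants < 1 || initial_mutants > N - 1)
    stop_invalid("`initial_mutants` must be an integer in [1, N - 1]")
  structure(
    list(N = as.integer(N), r = as.numeric(r),
         division_rate = as.numeric(division_rate),
         initial_mutants = as.integer(initial_mutants)),
    class = "moran_params"
  )
}

#' @export
print.moran_params <- function(x, ...) {
  cat(sprintf(
    "Moran process: N = %d, r = %g, division rate = %g/yr, %d initial mutant(s)\n",
    x$N, x$r, x$division_rate, x$initial_mutants))
  invisible(x)
}

#' Literature bounds on the stem-cell compartment size
#'
#' Lower and upper bounds on the number of actively contributing hematopoietic
#' stem cells used for sensitivity analysis, alongside the baseline 100,000.
#'
#' @return Named numeric vector with elements `lower`, `baseline`, `upper`.
#' @export
moran_N_bounds <- function() {
  c(lower = 25000, baseline = 100000, upper = 1300000)
}

#' One-step transition probabilities of the mutant-count chain
#'
#' The two-type Moran process reduces exactly to a birth-death chain on the
#' mutant count `k`: at each iteration one cell divides (probability
#' proportional to fitness) and one dies (uniformly; possibly the same cell).
#' With `k` mutants of fitness `r` among `N` cells,
#' `p_up = [r k / (r k + N - k)] * [(N - k) / N]` and
#' `p_down = [(N - k) / (r k + N - k)] * [k / N]`; the chain otherwise stays
#' put. States 0 and `N` are absorbing. At every interior state
#' `p_up / p_down = r`.
#'
#' @param params a [moran_parameters()] object.
#' @param k mutant count, vectorised over `0:N`.
#' @return A data frame with columns `k`, `p_up`, `p_down`, `p_stay`.
#' @export
step_probabilities <- function(params, k) {
  stopifnot(inherits(params, "moran_params"))
  N <- params$N; r <- params$r
  if (any(k < 0 | k > N | k != round(k)))
    stop_invalid("`k` must be integer(s) in [0, N]")
  denom <- r * k + (N - k)
  p_up <- (r * k / denom) * ((N - k) / N)
  p_down <- ((N - k) / denom) * (k / N)
  data.frame(k = k, p_up = p_up, p_down = p_down, p_stay = 1 - p_up - p_down)
}
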