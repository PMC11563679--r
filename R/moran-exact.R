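#' Exact fixation probability of the mutant lineage
#'
#' Closed-form hitting probability of state `N` for the mutant-count
#' birth-death chain. Starting from `k` mutants the probability is
#' `(1 - r^-k) / (1 - r^-N)` for \eqn{r \ne 1} and `k / N` in the neutral case.
#' Evaluated via `expm1()` on the log scale so the result is numerically
#' stable for `r` close to 1 and very large `N`.
#'
#' @param params a [moran_parameters()] object; `initial_mutants` sets the
#'   starting state.
#' @return Fixation probability in `[0, 1]`.
#' @examples
#' exact_fixation_probability(moran_parameters(N = 10, r = 2)) # ~0.50049
#' @export
exact_fixation_probability <- function(params) {
  stopifnot(inherits(params, "moran_params"))
  N <- params$N; r <- params$r; k <- params$initial_mutants
  if (r == 1) return(k / N)
  lr <- log(r)
  # (1 - exp(-k lr)) / (1 - exp(-N lr)); both differences via expm1
  expm1(-k * lr) / expm1(-N * lr)
}

# Conditioned (Doob h-transform) transition rates of the interior chain,
# shared by the exact conditional-time solver. h(k) is the fixation
# probability from k.
.fixation_h <- function(N, r, k) {
  if (r == 1) return(k / N)
  lr <- log(r)
  expm1(-k * lr) / expm1(-N * lr)
}

#' Exact mean conditional fixation time (iterations)
#'
#' Expected number of Moran iterations for the mutant lineage to reach
#' fixation, conditioned on fixation, starting from `initial_mutants`
#' cells. Computed by first-step analysis on the mutant-count chain after a
#' Doob h-transform with the fixation probability, which conditions the chain
#' on absorption at `N`; the resulting tridiagonal linear system is solved by
#' the Thomas algorithm in O(N). Iterations in which the same cell divides
#' and dies (self-replacement) are counted.
#'
#' @param params a [moran_parameters()] object.
#' @param max_N guard for the dense solve; above it the caller is directed to
#'   [simulate_fixation()] or [approximate_fixation_time()]. Default 2000.
#' @return Expected iterations to fixation, conditioned on fixation.
#' @examples
#' exact_conditional_fixation_time(moran_parameters(N = 2, r = 1)) # 2
#' @export
exact_conditional_fixation_time <- function(params, max_N = 2000) {
  stopifnot(inherits(params, "moran_params"))
  N <- params$N; r <- params$r; k0 <- params$initial_mutants
  if (N > max_N)
    stop_invalid(paste0(
      "N = %d exceeds the exact-solver limit (%d); use simulate_fixation() ",
      "or approximate_fixation_time() for large compartments"), N, max_N)
  k <- seq_len(N - 1)
  denom <- r * k + (N - k)
  p_up <- (r * k / denom) * ((N - k) / N)
  p_down <- ((N - k) / denom) * (k / N)
  h <- .fixation_h(N, r, 0:N)
  q_up <- p_up * h[k + 2L] / h[k + 1L]
  q_down <- p_down * h[k] / h[k + 1L]        # q_down[1] = 0 since h(0) = 0
  # (q_up + q_down) t_k - q_up t_{k+1} - q_down t_{k-1} = 1, t_N = 0
  b <- q_up + q_down
  cvec <- -q_up
  avec <- -q_down
  n <- N - 1L
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- cvec[1] / b[1]
  dp[1] <- 1 / b[1]
  if (n > 1) {
    for (i in 2:n) {
      m <- b[i] - avec[i] * cp[i - 1]
      cp[i] <- cvec[i] / m
      dp[i] <- (1 - avec[i] * dp[i - 1]) / m
    }
  }
  t <- numeric(n)
  t[n] <- dp[n]                              # t_{N} = 0 closes the recursion
  if (n > 1) for (i in (n - 1):1) t[i] <- dp[i] - cp[i] * t[i + 1]
  t[k0]
}
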