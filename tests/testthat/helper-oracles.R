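# Independent dense-matrix oracles for the mutant-count birth-death chain.
# Built from the full transition matrix and generic linear solves, sharing no
# code with the package's closed-form / Thomas-algorithm implementations.

oracle_transition_matrix <- function(N, r) {
  P <- matrix(0, N + 1, N + 1)
  for (k in 0:N) {
    i <- k + 1
    if (k == 0 || k == N) { P[i, i] <- 1; next }
    denom <- r * k + (N - k)
    up <- (r * k / denom) * ((N - k) / N)
    down <- ((N - k) / denom) * (k / N)
    P[i, i + 1] <- up
    P[i, i - 1] <- down
    P[i, i] <- 1 - up - down
  }
  P
}

# Hitting probability of state N from every state, by dense linear solve of
# the harmonic system.
oracle_fixation_probability <- function(N, r, k0 = 1) {
  P <- oracle_transition_matrix(N, r)
  trans <- 2:N                       # states 1..N-1
  A <- diag(N - 1) - P[trans, trans, drop = FALSE]
  b <- P[trans, N + 1]               # one-step mass into state N
  h <- solve(A, b)
  h[k0]
}

# Mean iterations to fixation conditioned on fixation, via the fundamental
# matrix of the h-conditioned dense chain.
oracle_conditional_fixation_time <- function(N, r, k0 = 1) {
  P <- oracle_transition_matrix(N, r)
  trans <- 2:N
  A <- diag(N - 1) - P[trans, trans, drop = FALSE]
  h <- c(0, solve(A, P[trans, N + 1]), 1)      # h over states 0..N
  Q <- P[trans, trans, drop = FALSE]
  hk <- h[trans]
  Qc <- Q * outer(1 / hk, hk)                  # q(k,j) = p(k,j) h(j)/h(k)
  t <- solve(diag(N - 1) - Qc, rep(1, N - 1))
  t[k0]
}

# z-score comparison helper for Monte-Carlo checks.
expect_within_3se <- function(estimate, truth, se) {
  expect_true(is.finite(se) && se > 0)
  expect_lt(abs(estimate - truth), 3 * se)
}
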