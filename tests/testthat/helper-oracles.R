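# Independent oracles used across the suite. These deliberately avoid the
# package's own evaluation paths: the impulse response is checked against
# direct ODE integration, step responses against an augmented closed form,
# and minimal dimensions against the block-Hankel rank.

# h(:, j) via ODE integration of the homogeneous system from kappa(0) = B e_j
# (the exact effect of a unit impulse on input j)
ode_impulse_oracle <- function(sys, times, rtol = 1e-10, atol = 1e-12) {
  deriv <- function(t, state, parms) list(as.numeric(sys$A %*% state))
  vals <- array(NA_real_, dim = c(length(times), sys$l, sys$m))
  tt <- sort(unique(c(0, times)))
  for (j in seq_len(sys$m)) {
    sol <- deSolve::lsoda(y = as.numeric(sys$B[, j]), times = tt,
                          func = deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    kry <- sol[match(times, tt), -1L, drop = FALSE]
    vals[, , j] <- matrix(kry, ncol = sys$n) %*% t(sys$C)
  }
  vals
}

# closed-form response to constant input u0 via an augmented matrix
# exponential: d/dt (kappa; 1) = [[A, B u0], [0, 0]] (kappa; 1)
step_response_oracle <- function(sys, u0, times) {
  n <- sys$n
  M <- rbind(cbind(sys$A, sys$B %*% u0), rep(0, n + 1))
  res <- vapply(times, function(t) {
    as.numeric((sys$C %*% as.matrix(Matrix::expm(M * t))[seq_len(n),
                                                         n + 1]))
  }, numeric(sys$l))
  matrix(res, nrow = length(times), ncol = sys$l, byrow = TRUE)
}

# dense time-sampled comparison of impulse responses (independent of the
# Markov-parameter certificate)
sampled_equivalent <- function(s1, s2, t_max = 4 * pi, points = 60,
                               tol = 1e-7) {
  ts <- seq(0, t_max, length.out = points)
  h1 <- impulse_response(s1, ts)$values
  h2 <- impulse_response(s2, ts)$values
  max(abs(h1 - h2)) <= tol * max(1, max(abs(h1)))
}

# random invertible matrix with a reciprocal-condition floor
random_invertible <- function(n, cond_floor = 1e-3) {
  repeat {
    V <- diag(n) + 0.4 * matrix(stats::runif(n * n, -1, 1), n, n)
    if (rcond(V) >= cond_floor) return(V)
  }
}

expect_system_equal <- function(s1, s2, tol = 1e-10) {
  expect_lt(max(abs(s1$A - s2$A)), tol)
  expect_lt(max(abs(s1$B - s2$B)), tol)
  expect_lt(max(abs(s1$C - s2$C)), tol)
}
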