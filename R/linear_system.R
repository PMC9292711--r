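#' Linear gene-network systems
#'
#' A gene regulatory network is modelled as the linear time-invariant system
#' \deqn{\dot\kappa(t) = A\kappa(t) + Bu(t), \qquad \phi(t) = C\kappa(t),}
#' with \eqn{\kappa(0) = 0}. The n-vector \eqn{\kappa(t)} of molecular
#' concentrations is the *kryptotype* (hidden from direct selection), the
#' m-vector \eqn{u(t)} is exogenous input, and the l-vector
#' \eqn{\phi(t)} is the *phenotype* on which selection acts. The entire
#' input-output behaviour is captured by the impulse response
#' \eqn{h(t) = C e^{At} B}.
#'
#' @param A n x n matrix of regulatory coefficients (units 1/time);
#'   `A[i,j]` is the effect of molecule j on the rate of change of
#'   molecule i.
#' @param B n x m input-coupling matrix.
#' @param C l x n output read-out matrix.
#' @return An object of class `linear_system`: a list with elements
#'   `A`, `B`, `C` and the dimensions `n`, `m`, `l`.
#' @examples
#' sys <- make_system(matrix(c(0, -1, 1, 0), 2, 2), c(1, 1), t(c(1, 0)))
#' sys$n
#' @seealso [oscillator()], [impulse_response()], [phenotypically_equivalent()]
#' @export
make_system <- function(A, B, C) {
  A <- as_real_matrix(A, "A")
  B <- as_real_matrix(B, "B")
  C <- as_real_matrix(C, "C")
  n <- nrow(A)
  if (ncol(A) != n)
    stop("A must be square, got ", n, " x ", ncol(A), call. = FALSE)
  if (nrow(B) != n)
    stop("dimension mismatch between A (", n, " x ", n, ") and B (",
         nrow(B), " x ", ncol(B), "): B must have ", n, " rows",
         call. = FALSE)
  if (ncol(C) != n)
    stop("dimension mismatch between A (", n, " x ", n, ") and C (",
         nrow(C), " x ", ncol(C), "): C must have ", n, " columns",
         call. = FALSE)
  structure(list(A = A, B = B, C = C,
                 n = n, m = ncol(B), l = nrow(C)),
            class = "linear_system")
}

# coerce to a matrix of finite numerics; vectors become single columns
as_real_matrix <- function(x, name) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(x) || !is.numeric(x))
    stop(name, " must be a numeric matrix", call. = FALSE)
  if (length(x) == 0L)
    stop(name, " must be nonempty", call. = FALSE)
  if (!all(is.finite(x)))
    stop(name, " contains non-finite entries", call. = FALSE)
  storage.mode(x) <- "double"
  unname(x)
}

#' @export
print.linear_system <- function(x, ...) {
  cat("<linear_system>  n =", x$n, " inputs m =", x$m, " outputs l =", x$l, "\n")
  cat("A:\n"); print(x$A)
  cat("B:\n"); print(x$B)
  cat("C:\n"); print(x$C)
  invisible(x)
}

#' @export
is_linear_system <- function(x) inherits(x, "linear_system")

# dense matrix exponential (scaling-and-squaring Pade, via Matrix)
expm_mat <- function(M) {
  if (nrow(M) == 1L) return(matrix(exp(M[1, 1]), 1, 1))
  as.matrix(Matrix::expm(M))
}

#' Impulse response of a linear system
#'
#' Evaluates \eqn{h(t) = C e^{At} B} on a grid of times. For an impulse
#' (delta-function) input the phenotype trajectory equals the impulse
#' response, and two systems have identical phenotypes for *every* input
#' exactly when their impulse responses agree.
#'
#' @param sys a `linear_system`.
#' @param times nondecreasing vector of nonnegative times.
#' @return An object of class `impulse_response`: list with `times` and
#'   `values`, an array of dimension `length(times) x l x m`.
#' @examples
#' h <- impulse_response(oscillator(), seq(0, 2 * pi, length.out = 9))
#' # the two-gene oscillator has h(t) = sin t + cos t
#' max(abs(drop(h$values) - (sin(h$times) + cos(h$times))))
#' @export
impulse_response <- function(sys, times) {
  stopifnot(is_linear_system(sys))
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and nonnegative", call. = FALSE)
  if (is.unsorted(times))
    stop("times must be nondecreasing", call. = FALSE)
  vals <- array(NA_real_, dim = c(length(times), sys$l, sys$m))
  for (k in seq_along(times)) {
    vals[k, , ] <- sys$C %*% expm_mat(sys$A * times[k]) %*% sys$B
  }
  structure(list(times = times, values = vals,
                 l = sys$l, m = sys$m),
            class = "impulse_response")
}

#' @export
print.impulse_response <- function(x, ...) {
  cat("<impulse_response>", length(x$times), "samples on [",
      min(x$times), ",", max(x$times), "], dim", x$l, "x", x$m, "\n")
  invisible(x)
}

#' Markov parameters of a linear system
#'
#' Returns the sequence \eqn{C A^k B} for \eqn{k = 0, \dots, count-1}.
#' These are the Taylor coefficients of the impulse response at
#' \eqn{t = 0} (up to factorials); two systems of state dimension
#' \eqn{n_1}, \eqn{n_2} have identical impulse responses for all
#' \eqn{t \ge 0} if and only if their first \eqn{n_1 + n_2} Markov
#' parameters agree (Cayley-Hamilton), which makes them a finite
#' certificate for phenotypic equivalence.
#'
#' @param sys a `linear_system`.
#' @param count number of parameters (>= 1).
#' @return list of `count` matrices, each l x m.
#' @export
markov_parameters <- function(sys, count) {
  stopifnot(is_linear_system(sys), count >= 1)
  out <- vector("list", count)
  M <- sys$B
  for (k in seq_len(count)) {
    out[[k]] <- sys$C %*% M
    if (k < count) M <- sys$A %*% M
  }
  out
}

#' Test phenotypic equivalence of two systems
#'
#' Two systems are phenotypically equivalent when their impulse responses
#' coincide for all \eqn{t \ge 0}: they then produce identical phenotype
#' trajectories for every admissible input. The test compares the first
#' \eqn{n_1 + n_2} Markov parameters, normalised by the largest parameter
#' magnitude, which is an exact finite certificate in exact arithmetic.
#' The systems may have different state dimensions but must share input
#' and output dimensions.
#'
#' @param sys1,sys2 `linear_system` objects with equal `m` and `l`.
#' @param tol relative tolerance on the Markov-parameter discrepancy
#'   (default `1e-8`).
#' @return `TRUE` or `FALSE`, with attribute `"discrepancy"` giving the
#'   normalised maximum deviation.
#' @examples
#' phenotypically_equivalent(oscillator(), oscillator_family(0.3))
#' @export
phenotypically_equivalent <- function(sys1, sys2, tol = 1e-8) {
  stopifnot(is_linear_system(sys1), is_linear_system(sys2))
  if (sys1$m != sys2$m || sys1$l != sys2$l)
    stop("systems must share input and output dimensions (m, l); got (",
         sys1$m, ",", sys1$l, ") vs (", sys2$m, ",", sys2$l, ")",
         call. = FALSE)
  count <- sys1$n + sys2$n
  mp1 <- markov_parameters(sys1, count)
  mp2 <- markov_parameters(sys2, count)
  scale <- max(1e-300,
               max(vapply(mp1, function(M) max(abs(M)), 0)),
               max(vapply(mp2, function(M) max(abs(M)), 0)))
  disc <- max(vapply(seq_len(count),
                     function(k) max(abs(mp1[[k]] - mp2[[k]])), 0)) / scale
  structure(disc <= tol, discrepancy = disc)
}

#' Apply an invertible change of coordinates to the kryptotype
#'
#' For invertible V the system \eqn{(VAV^{-1}, VB, CV^{-1})} has the same
#' impulse response as \eqn{(A, B, C)}: the change of basis cancels inside
#' \eqn{C e^{At} B}. Biologically this rewires regulatory interactions
#' (entries of A can change magnitude and sign) without any phenotypic
#' consequence.
#'
#' @param sys a `linear_system`.
#' @param V invertible n x n matrix.
#' @param rcond_tol reciprocal-condition-number guard below which V is
#'   rejected as numerically singular (default `1e-12`).
#' @return the transformed `linear_system`.
#' @export
coordinate_change <- function(sys, V, rcond_tol = 1e-12) {
  stopifnot(is_linear_system(sys))
  V <- as_real_matrix(V, "V")
  if (nrow(V) != sys$n || ncol(V) != sys$n)
    stop("V must be ", sys$n, " x ", sys$n, call. = FALSE)
  rc <- rcond(V)
  if (!is.finite(rc) || rc < rcond_tol)
    stop("V is singular or near-singular (rcond = ", format(rc), ")",
         call. = FALSE)
  Vi <- solve(V)
  make_system(V %*% sys$A %*% Vi, V %*% sys$B, sys$C %*% Vi)
}

#' Simulate kryptotype and phenotype trajectories
#'
#' Integrates \eqn{\dot\kappa = A\kappa + Bu(t)} from \eqn{\kappa(0)=0}
#' with `deSolve` and reads out \eqn{\phi = C\kappa}. The phenotype then
#' equals the convolution of the input with the impulse response.
#'
#' Since a true delta function cannot be sampled, [impulse_input()]
#' provides a rectangular unit-mass pulse; as its width shrinks the
#' simulated phenotype converges to the impulse response. Input functions
#' may carry a `"breakpoints"` attribute (times of discontinuity) which is
#' used to split the integration so the solver cannot step over a narrow
#' pulse.
#'
#' @param sys a `linear_system`.
#' @param u input: a function of time returning an m-vector (or scalar
#'   recycled to m).
#' @param times nondecreasing nonnegative output times.
#' @param rtol,atol solver tolerances passed to [deSolve::lsoda()].
#' @return A `trajectory`: list with `times`, `kryptotype`
#'   (length(times) x n), `phenotype` (x l), `input` (x m).
#' @examples
#' tr <- simulate(oscillator(), function(t) rep(1, 1), seq(0, pi, length.out = 20))
#' @export
simulate <- function(sys, u, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(is_linear_system(sys), is.function(u))
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0) || is.unsorted(times))
    stop("times must be finite, nonnegative and nondecreasing", call. = FALSE)
  uval <- function(t) {
    v <- u(t)
    if (length(v) == 1L && sys$m > 1L) v <- rep(v, sys$m)
    if (length(v) != sys$m || any(!is.finite(v)))
      stop("input function returned a non-finite or wrongly sized value at t = ",
           t, call. = FALSE)
    as.numeric(v)
  }
  deriv <- function(t, state, parms) {
    list(as.numeric(sys$A %*% state + sys$B %*% uval(t)))
  }
  # integrate piecewise between input discontinuities so the solver
  # restarts at each breakpoint and cannot step over a narrow pulse
  tmax <- max(times, 0)
  brk <- attr(u, "breakpoints")
  edges <- sort(unique(c(0, brk[is.finite(brk) & brk > 0 & brk < tmax],
                         tmax)))
  kry <- matrix(NA_real_, length(times), sys$n)
  kry[times == 0, ] <- 0
  state <- rep(0, sys$n)
  if (tmax > 0) {
    for (seg in seq_len(length(edges) - 1L)) {
      t0 <- edges[seg]; t1 <- edges[seg + 1L]
      want <- times > t0 & times <= t1
      seg_times <- sort(unique(c(t0, times[want], t1)))
      sol <- deSolve::lsoda(y = state, times = seg_times, func = deriv,
                            parms = NULL, rtol = rtol, atol = atol)
      state <- as.numeric(sol[nrow(sol), -1L])
      kry[want, ] <- sol[match(times[want], seg_times), -1L]
    }
  }
  phen <- kry %*% t(sys$C)
  inp <- t(vapply(times, uval, numeric(sys$m)))
  inp <- matrix(inp, nrow = length(times), ncol = sys$m)
  structure(list(times = times, kryptotype = kry, phenotype = phen,
                 input = inp),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$times), "samples on [",
      min(x$times), ",", max(x$times), "], n =", ncol(x$kryptotype),
      " l =", ncol(x$phenotype), "\n")
  invisible(x)
}

#' Rectangular approximation to a unit impulse at time zero
#'
#' Returns a function of time equal to `1/width` on `[0, width)` and zero
#' afterwards (unit mass). As `width` shrinks the response of any system
#' to this input converges to its impulse response.
#'
#' @param width pulse width in time units (default `1e-3`).
#' @param m input dimension (default 1).
#' @export
impulse_input <- function(width = 1e-3, m = 1) {
  stopifnot(width > 0)
  f <- function(t) if (t >= 0 && t < width) rep(1 / width, m) else rep(0, m)
  attr(f, "breakpoints") <- c(0, width)
  f
}

#' The two-gene oscillator
#'
#' A minimal two-gene network in which gene 2 upregulates gene 1, gene 1
#' downregulates gene 2 with equal strength, both genes receive the same
#' exogenous input, and only gene 1 is read out:
#' \eqn{A = [[0, 1], [-1, 0]]}, \eqn{B = (1, 1)^T}, \eqn{C = (1, 0)}.
#' Its impulse response is \eqn{h(t) = \sin t + \cos t}, a caricature of
#' oscillating transcription as in cell-cycle or circadian control.
#'
#' @return a `linear_system` with n = 2, m = 1, l = 1.
#' @export
oscillator <- function() {
  make_system(matrix(c(0, -1, 1, 0), 2, 2),
              matrix(c(1, 1), 2, 1),
              matrix(c(1, 0), 1, 2))
}

#' The one-parameter family of rewired oscillators
#'
#' All two-gene systems phenotypically equivalent to [oscillator()] that
#' keep B and C fixed form a one-parameter family
#' \deqn{A(\tau) = \frac{1}{\tau+1}
#'   \begin{pmatrix} \tau & 1 \\ -(2\tau(\tau+1)+1) & -\tau \end{pmatrix},
#'   \quad \tau \neq -1,}
#' obtained as \eqn{V A(0) V^{-1}} with
#' \eqn{V = [[1, 0], [-\tau, \tau+1]]}, the general invertible matrix
#' satisfying \eqn{VB = B} and \eqn{CV = C}. Every member has the impulse
#' response \eqn{\sin t + \cos t}; regulatory interactions nevertheless
#' change strength and even sign along the family.
#'
#' @param tau family parameter, `tau != -1`.
#' @param tol guard half-width around the singular value -1.
#' @return a `linear_system`.
#' @examples
#' phenotypically_equivalent(oscillator_family(-2), oscillator())
#' @export
oscillator_family <- function(tau, tol = 1e-8) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (abs(tau + 1) <= tol)
    stop("oscillator family is undefined at tau = -1", call. = FALSE)
  A <- matrix(c(tau, -(2 * tau * (tau + 1) + 1), 1, -tau), 2, 2) / (tau + 1)
  make_system(A, matrix(c(1, 1), 2, 1), matrix(c(1, 0), 1, 2))
}

#' Reproducible pseudo-random linear system
#'
#' Draws entries of A, B, C iid standard normal under a local seed, then
#' optionally shifts the diagonal of A so that the largest real part of
#' its eigenvalues is at most `spectral_bound` (producing a stable system
#' for negative bounds). Used as a fixture generator; the local RNG scope
#' leaves the caller's RNG state untouched.
#'
#' @param n,m,l state, input and output dimensions.
#' @param seed integer seed.
#' @param spectral_bound optional upper bound on eigenvalue real parts.
#' @return a `linear_system`.
#' @export
random_system <- function(n, m = 1, l = 1, seed = 1, spectral_bound = NULL) {
  stopifnot(n >= 1, m >= 1, l >= 1)
  st <- local_rng(seed)
  on.exit(restore_rng(st))
  A <- matrix(stats::rnorm(n * n), n, n)
  B <- matrix(stats::rnorm(n * m), n, m)
  C <- matrix(stats::rnorm(l * n), l, n)
  if (!is.null(spectral_bound)) {
    shift <- max(Re(eigen(A, only.values = TRUE)$values)) - spectral_bound
    if (shift > 0) A <- A - diag(shift, n)
  }
  make_system(A, B, C)
}

# Temporarily set the RNG; returns previous state for restore_rng().
local_rng <- function(seed) {
  st <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  st
}

restore_rng <- function(st) {
  if (is.null(st)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", st, envir = globalenv())
  }
  invisible(NULL)
}
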