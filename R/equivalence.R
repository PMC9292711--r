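# Subspace geometry of the phenotypic-equivalence set: reachability,
# observability, the Kalman decomposition, minimal realizations, and the
# neutral tangent directions available to evolution.

# orthonormal basis of the column span of M. Rank is decided against
# rank_tol * max(largest singular value, ref): ref = 0 scales to the
# matrix itself; ref = 1 is used where the input is built from
# orthonormal bases, so that a residual that is zero up to roundoff is
# recognized as empty rather than rescaled into a spurious direction.
orth_basis <- function(M, rank_tol = 1e-9, ref = 0) {
  if (is.null(M) || length(M) == 0L || all(M == 0))
    return(matrix(0, nrow = max(nrow(M), 1L), ncol = 0))
  sv <- svd(M)
  r <- sum(sv$d > rank_tol * max(sv$d, ref))
  sv$u[, seq_len(r), drop = FALSE]
}

# orthonormal basis of the null space of M (columns x satisfying Mx = 0)
null_basis <- function(M, rank_tol = 1e-9) {
  n <- ncol(M)
  if (nrow(M) == 0L || all(M == 0)) return(diag(n))
  sv <- svd(M, nu = 0, nv = n)
  r <- sum(sv$d > rank_tol * max(sv$d))
  sv$v[, seq(r + 1, length.out = n - r), drop = FALSE]
}

# orthonormal basis of span(U) intersect span(W); U, W orthonormal columns
subspace_intersection <- function(U, W, rank_tol = 1e-9) {
  n <- nrow(U)
  if (ncol(U) == 0L || ncol(W) == 0L) return(matrix(0, n, 0))
  # x in both spans <=> x = U a = W b; null space of [U, -W] gives (a; b)
  N <- null_basis(cbind(U, -W), rank_tol)
  if (ncol(N) == 0L) return(matrix(0, n, 0))
  orth_basis(U %*% N[seq_len(ncol(U)), , drop = FALSE], rank_tol, ref = 1)
}

# orthonormal basis of the part of span(U) orthogonal to span(S)
subspace_complement_within <- function(U, S, rank_tol = 1e-9) {
  if (ncol(U) == 0L) return(U)
  if (ncol(S) == 0L) return(U)
  resid <- U - S %*% (t(S) %*% U)
  orth_basis(resid, rank_tol, ref = 1)
}

#' Reachable subspace of a linear system
#'
#' The set of kryptotype directions that some input history can excite:
#' the column span of the controllability matrix
#' \eqn{[B, AB, A^2B, \dots, A^{n-1}B]}. Directions outside it can never
#' respond to the environment, whatever the input.
#'
#' @param sys a `linear_system`.
#' @param rank_tol relative singular-value threshold for rank decisions.
#' @return matrix with orthonormal columns spanning the reachable
#'   subspace (zero columns if B = 0).
#' @export
reachable_subspace <- function(sys, rank_tol = 1e-9) {
  stopifnot(is_linear_system(sys))
  orth_basis(controllability_matrix(sys), rank_tol)
}

controllability_matrix <- function(sys) {
  blocks <- vector("list", sys$n)
  M <- sys$B
  for (k in seq_len(sys$n)) {
    blocks[[k]] <- M
    if (k < sys$n) M <- sys$A %*% M
  }
  do.call(cbind, blocks)
}

observability_matrix <- function(sys) {
  blocks <- vector("list", sys$n)
  M <- sys$C
  for (k in seq_len(sys$n)) {
    blocks[[k]] <- M
    if (k < sys$n) M <- M %*% sys$A
  }
  do.call(rbind, blocks)
}

#' Unobservable subspace of a linear system
#'
#' The largest A-invariant subspace contained in the null space of C:
#' kryptotype motion inside it never shows up in the phenotype. Computed
#' as the null space of the stacked observability matrix
#' \eqn{[C; CA; \dots; CA^{n-1}]}.
#'
#' @inheritParams reachable_subspace
#' @return matrix with orthonormal columns spanning the unobservable
#'   subspace.
#' @export
unobservable_subspace <- function(sys, rank_tol = 1e-9) {
  stopifnot(is_linear_system(sys))
  n <- sys$n
  O <- observability_matrix(sys)
  if (all(O == 0)) return(diag(n))
  null_basis(O, rank_tol)
}

#' Kalman decomposition of a linear system
#'
#' Finds a change of basis P splitting the kryptotype space into four
#' blocks ordered (reachable & unobservable, reachable & observable,
#' unreachable & unobservable, unreachable & observable). In the new
#' coordinates \eqn{(PAP^{-1}, PB, CP^{-1})}, A is block
#' upper-triangular with the pattern enforced by invariance of the
#' reachable and unobservable subspaces, B is supported on the two
#' reachable blocks and C on the two observable blocks. Only the
#' reachable-and-observable block shapes the phenotype:
#' \eqn{h(t) = C_{ro} e^{A_{ro} t} B_{ro}}, so every other block is an
#' evolutionary degree of freedom.
#'
#' @inheritParams reachable_subspace
#' @return A `kalman_decomposition`: list with `P`, `Pinv`, `dims`
#'   (named vector `ro_bar`, `ro`, `rbar_obar`, `rbar_o` summing to n),
#'   `transformed` (the triple in the new basis, a `linear_system`),
#'   `minimal` (the extracted reachable-observable `linear_system`), and
#'   `rank_warnings` (character, nonempty when singular values straddle
#'   the rank threshold within a factor of 10).
#' @export
kalman_decomposition <- function(sys, rank_tol = 1e-9) {
  stopifnot(is_linear_system(sys))
  n <- sys$n
  warnings <- character(0)
  for (M in list(controllability_matrix(sys), observability_matrix(sys))) {
    sv <- svd(M)$d
    thr <- rank_tol * max(sv, 1e-300)
    if (any(sv > thr / 10 & sv < thr * 10 & sv != max(sv)))
      warnings <- c(warnings,
                    "singular values near the rank threshold; subspace dimensions may be ambiguous")
  }
  R <- reachable_subspace(sys, rank_tol)
  UO <- unobservable_subspace(sys, rank_tol)
  T1 <- subspace_intersection(R, UO, rank_tol)          # reachable & unobservable
  T2 <- subspace_complement_within(R, T1, rank_tol)     # reachable & observable
  T3 <- subspace_complement_within(UO, T1, rank_tol)    # unreachable & unobservable
  T123 <- cbind(T1, T2, T3)
  T4 <- if (ncol(T123) == 0L) diag(n) else
    null_basis(t(T123), rank_tol)                        # remainder (unreachable & observable)
  Tmat <- cbind(T1, T2, T3, T4)
  if (ncol(Tmat) != n)
    stop("internal error: Kalman basis has ", ncol(Tmat),
         " columns, expected ", n, call. = FALSE)
  P <- solve(Tmat)
  dims <- c(ro_bar = ncol(T1), ro = ncol(T2),
            rbar_obar = ncol(T3), rbar_o = ncol(T4))
  At <- P %*% sys$A %*% Tmat
  Bt <- P %*% sys$B
  Ct <- sys$C %*% Tmat
  idx_ro <- seq(dims[["ro_bar"]] + 1, length.out = dims[["ro"]])
  minimal <- if (dims[["ro"]] > 0) {
    make_system(At[idx_ro, idx_ro, drop = FALSE],
                Bt[idx_ro, , drop = FALSE],
                Ct[, idx_ro, drop = FALSE])
  } else {
    # no reachable-observable part: the phenotype is identically zero;
    # represent the minimal system as a 1-state zero system
    make_system(matrix(0, 1, 1), matrix(0, 1, sys$m), matrix(0, sys$l, 1))
  }
  structure(list(P = P, Pinv = Tmat, dims = dims,
                 transformed = make_system(At, Bt, Ct),
                 minimal = minimal,
                 rank_warnings = unique(warnings)),
            class = "kalman_decomposition")
}

#' @export
print.kalman_decomposition <- function(x, ...) {
  cat("<kalman_decomposition> dims:",
      paste(names(x$dims), x$dims, sep = "=", collapse = " "), "\n")
  if (length(x$rank_warnings))
    cat("warnings:", paste(x$rank_warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Minimal realization of a linear system
#'
#' Extracts the reachable-and-observable block of the Kalman
#' decomposition: the phenotypically equivalent system of smallest state
#' dimension, unique up to change of coordinates. Its dimension equals
#' the rank of the block-Hankel matrix of Markov parameters.
#'
#' @inheritParams reachable_subspace
#' @return a `linear_system` of minimal dimension, phenotypically
#'   equivalent to `sys` (except for the degenerate zero-response case,
#'   where a 1-state zero system is returned).
#' @export
minimal_realization <- function(sys, rank_tol = 1e-9) {
  kalman_decomposition(sys, rank_tol)$minimal
}

#' Rank of the block-Hankel matrix of Markov parameters
#'
#' Independent certificate of minimal state dimension: the rank of
#' \eqn{H_{ij} = C A^{i+j} B}, for \eqn{i, j = 0, \dots, n-1}, equals the
#' dimension of any minimal realization.
#'
#' @inheritParams reachable_subspace
#' @return integer rank.
#' @export
hankel_rank <- function(sys, rank_tol = 1e-9) {
  stopifnot(is_linear_system(sys))
  n <- sys$n
  mp <- markov_parameters(sys, 2 * n - 1)
  H <- matrix(0, n * sys$l, n * sys$m)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    H[(i - 1) * sys$l + seq_len(sys$l),
      (j - 1) * sys$m + seq_len(sys$m)] <- mp[[i + j - 1]]
  }
  if (all(H == 0)) return(0L)
  sv <- svd(H)$d
  sum(sv > rank_tol * max(sv))
}

#' Embed a system in a larger, phenotypically equivalent one
#'
#' Grows the state dimension by `n_extra` genes whose couplings are
#' randomized only within the blocks the Kalman form leaves free, then
#' hides the block structure behind a random well-conditioned change of
#' basis. The impulse response is unchanged by construction: gene
#' networks can carry arbitrarily many phenotypically silent components,
#' each adding evolutionary degrees of freedom.
#'
#' @param sys a `linear_system` (treated as the reachable-observable
#'   core).
#' @param n_extra number of extra state dimensions (>= 1).
#' @param classes character vector recycled to length `n_extra`,
#'   assigning each extra dimension to `"ro_bar"` (reachable,
#'   unobservable), `"rbar_obar"` (unreachable, unobservable) or
#'   `"rbar_o"` (unreachable, observable).
#' @param seed integer seed for the randomized couplings.
#' @param scramble if `TRUE` (default) conjugate by a random
#'   well-conditioned matrix so the block structure is not visible.
#' @return a `linear_system` with `sys$n + n_extra` states.
#' @export
pad_nonminimal <- function(sys, n_extra, classes = "rbar_obar", seed = 1,
                           scramble = TRUE) {
  stopifnot(is_linear_system(sys), n_extra >= 1)
  classes <- match.arg(rep(classes, length.out = n_extra),
                       c("ro_bar", "rbar_obar", "rbar_o"),
                       several.ok = TRUE)
  if (length(classes) == 0L) stop("classes must be nonempty", call. = FALSE)
  st <- local_rng(seed)
  on.exit(restore_rng(st))
  runifm <- function(r, c) matrix(stats::runif(r * c, -1, 1), r, c)
  # order indices: ro_bar extras | ro core | rbar_obar extras | rbar_o extras
  i1 <- which(classes == "ro_bar")
  i3 <- which(classes == "rbar_obar")
  i4 <- which(classes == "rbar_o")
  n1 <- length(i1); n2 <- sys$n; n3 <- length(i3); n4 <- length(i4)
  N <- n1 + n2 + n3 + n4
  A <- matrix(0, N, N)
  b1 <- seq_len(n1)
  b2 <- n1 + seq_len(n2)
  b3 <- n1 + n2 + seq_len(n3)
  b4 <- n1 + n2 + n3 + seq_len(n4)
  A[b2, b2] <- sys$A
  # allowed off-diagonal couplings in the block upper-triangular pattern
  if (n1) {
    A[b1, b1] <- runifm(n1, n1)
    if (n2) A[b1, b2] <- runifm(n1, n2)
    if (n3) A[b1, b3] <- runifm(n1, n3)
    if (n4) A[b1, b4] <- runifm(n1, n4)
  }
  if (n3) {
    A[b3, b3] <- runifm(n3, n3)
    if (n4) A[b3, b4] <- runifm(n3, n4)
  }
  if (n4) A[b4, b4] <- runifm(n4, n4)
  if (n2 && n4) A[b2, b4] <- runifm(n2, n4)
  B <- matrix(0, N, sys$m)
  B[b2, ] <- sys$B
  if (n1) B[b1, ] <- runifm(n1, sys$m)
  C <- matrix(0, sys$l, N)
  C[, b2] <- sys$C
  if (n4) C[, b4] <- runifm(sys$l, n4)
  out <- make_system(A, B, C)
  if (scramble) {
    V <- diag(N) + 0.3 * runifm(N, N)
    while (rcond(V) < 1e-3) V <- diag(N) + 0.3 * runifm(N, N)
    out <- coordinate_change(out, V)
  }
  out
}

#' Neutral tangent directions of the equivalence set
#'
#' First-order neutral perturbations of (A, B, C) come from generator
#' matrices Z via \eqn{(\Delta A, \Delta B, \Delta C) =
#' (ZA - AZ, ZB, -CZ)}: the perturbed system is the conjugation of the
#' original by \eqn{e^{\epsilon Z}} to first order, so its phenotype is
#' unchanged to second order in the step. Constraint modes restrict the
#' admissible Z:
#' \describe{
#'   \item{`free`}{all of the n x n matrix space (B, C allowed to move).}
#'   \item{`fixed_B`}{`ZB = 0` (input coupling held fixed).}
#'   \item{`fixed_C`}{`CZ = 0` (read-out held fixed).}
#'   \item{`fixed_BC`}{`ZB = 0` and `CZ = 0` (only A moves). For generic
#'     (A, B, C) the dimension is `n * (n - l - m)`, but degenerate
#'     configurations (such as the two-gene oscillator, where the null
#'     space is 1-dimensional) are reported as computed.}
#' }
#'
#' @param sys a `linear_system`.
#' @param constraint_mode one of `"free"`, `"fixed_B"`, `"fixed_C"`,
#'   `"fixed_BC"`.
#' @param rank_tol singular-value threshold for the constraint null
#'   space.
#' @return A `neutral_tangent`: list with `Z` (list of generator
#'   matrices, orthonormal under the Frobenius inner product),
#'   `generators` (list of triples `dA`, `dB`, `dC`), `dimension`,
#'   `constraint_mode`, and `generic_dimension` (the reference value
#'   `n*(n-l-m)` for mode `fixed_BC`, `NA` otherwise).
#' @export
neutral_tangent <- function(sys, constraint_mode = c("fixed_BC", "free",
                                                     "fixed_B", "fixed_C"),
                            rank_tol = 1e-9) {
  stopifnot(is_linear_system(sys))
  constraint_mode <- match.arg(constraint_mode)
  n <- sys$n
  constraints <- switch(constraint_mode,
    free = matrix(0, 0, n * n),
    # vec(ZB) = (t(B) %x% I) vec(Z); vec(CZ) = (I %x% C) vec(Z)
    fixed_B = t(sys$B) %x% diag(n),
    fixed_C = diag(n) %x% sys$C,
    fixed_BC = rbind(t(sys$B) %x% diag(n), diag(n) %x% sys$C))
  basis <- null_basis(constraints, rank_tol)
  Zs <- lapply(seq_len(ncol(basis)),
               function(k) matrix(basis[, k], n, n))
  gens <- lapply(Zs, function(Z)
    list(dA = Z %*% sys$A - sys$A %*% Z,
         dB = Z %*% sys$B,
         dC = -sys$C %*% Z))
  structure(list(Z = Zs, generators = gens, dimension = length(Zs),
                 constraint_mode = constraint_mode,
                 generic_dimension = if (constraint_mode == "fixed_BC")
                   n * (n - sys$l - sys$m) else NA_integer_),
            class = "neutral_tangent")
}

#' @export
print.neutral_tangent <- function(x, ...) {
  cat("<neutral_tangent> mode", x$constraint_mode,
      " dimension", x$dimension)
  if (!is.na(x$generic_dimension))
    cat("  (generic reference:", x$generic_dimension, ")")
  cat("\n")
  invisible(x)
}

#' Step a system along a neutral tangent generator
#'
#' Applies the first-order perturbation
#' \eqn{(A + \epsilon(ZA - AZ), B + \epsilon ZB, C - \epsilon CZ)}.
#' The resulting system's distance to the original optimum scales as
#' \eqn{\epsilon^2}, the numerical signature of first-order neutrality.
#'
#' @param sys a `linear_system`.
#' @param generator one element of `neutral_tangent(...)$generators`.
#' @param eps step size.
#' @return a `linear_system`.
#' @export
tangent_step <- function(sys, generator, eps) {
  make_system(sys$A + eps * generator$dA,
              sys$B + eps * generator$dB,
              sys$C + eps * generator$dC)
}
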