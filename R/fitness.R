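# The weighted phenotypic distance-to-optimum functional
#   D(h) = ( int_0^T rho(t) ||h(t) - h0(t)||^2 dt )^(1/2),  rho(t) = e^(-sigma t)
# and the hybrid-breakdown experiments built on it.

#' Specify a distance-to-optimum functional
#'
#' The fitness-relevant mismatch between a system's impulse response h
#' and the optimal response h0 is the weighted L2 distance
#' \deqn{D(h) = \Big(\int_0^T e^{-\sigma t}\,\|h(t) - h_0(t)\|^2\,dt\Big)^{1/2}.}
#' The default decay rate \eqn{\sigma = 1/(4\pi)} weights the dynamics
#' over a few multiples of \eqn{2\pi} and discounts later times.
#'
#' Three evaluation methods are available:
#' \describe{
#'   \item{`gramian`}{finite horizon T: exact evaluation through a single
#'     matrix exponential of an augmented block matrix (a finite-horizon
#'     observability Gramian); fast and quadrature-free.}
#'   \item{`quadrature`}{adaptive quadrature of the integrand (finite or
#'     infinite horizon); the integrand is evaluated from the matrix
#'     exponential.}
#'   \item{`lyapunov`}{infinite horizon only: solves the continuous-time
#'     Lyapunov equation of the \eqn{\sigma/2}-shifted augmented system;
#'     valid only when that shifted system is strictly stable, and
#'     reports divergence otherwise.}
#'   \item{`auto`}{(default) `lyapunov` when `horizon = Inf`, else
#'     `gramian`.}
#' }
#'
#' With an infinite horizon the integral diverges whenever the shifted
#' augmented system has an eigenvalue with nonnegative real part; the
#' distance is then `+Inf` (a divergence signal, not a numerical
#' failure).
#'
#' @param optimum a `linear_system` whose impulse response is the
#'   optimum h0.
#' @param sigma exponential decay rate of the weight (default
#'   `1/(4*pi)`).
#' @param horizon upper integration limit T; `Inf` for the unbounded
#'   functional.
#' @param method see Details.
#' @return an object of class `distance_spec`.
#' @export
distance_spec <- function(optimum, sigma = 1 / (4 * pi), horizon = Inf,
                          method = c("auto", "gramian", "quadrature",
                                     "lyapunov")) {
  stopifnot(is_linear_system(optimum), sigma > 0, horizon > 0)
  method <- match.arg(method)
  if (method == "auto")
    method <- if (is.infinite(horizon)) "lyapunov" else "gramian"
  if (method == "lyapunov" && is.finite(horizon))
    stop("the lyapunov method evaluates the unbounded-horizon functional; ",
         "use method 'gramian' or 'quadrature' for a finite horizon",
         call. = FALSE)
  if (method == "gramian" && is.infinite(horizon))
    stop("the gramian method needs a finite horizon", call. = FALSE)
  structure(list(optimum = optimum, sigma = sigma, horizon = horizon,
                 method = method),
            class = "distance_spec")
}

# stacked system whose impulse response is h(t) - h0(t)
augmented_difference <- function(sys, optimum) {
  n1 <- sys$n; n2 <- optimum$n
  A <- matrix(0, n1 + n2, n1 + n2)
  A[seq_len(n1), seq_len(n1)] <- sys$A
  A[n1 + seq_len(n2), n1 + seq_len(n2)] <- optimum$A
  list(A = A, B = rbind(sys$B, optimum$B), C = cbind(sys$C, -optimum$C))
}

# largest real part of eigenvalues of the sigma/2-shifted augmented matrix
shifted_abscissa <- function(sys, spec) {
  aug <- augmented_difference(sys, spec$optimum)
  max(Re(eigen(aug$A, only.values = TRUE)$values)) - spec$sigma / 2
}

#' Is a system's unbounded-horizon distance to the optimum divergent?
#'
#' `TRUE` when the \eqn{\sigma/2}-shifted augmented system of `sys` and
#' the optimum is not strictly stable, so that the infinite-horizon
#' weighted L2 distance is `+Inf`.
#'
#' @param sys a `linear_system`.
#' @param spec a `distance_spec`.
#' @param margin stability margin: divergent when the largest shifted
#'   eigenvalue real part exceeds `-margin`.
#' @export
is_divergent <- function(sys, spec, margin = 1e-12) {
  shifted_abscissa(sys, spec) >= -margin
}

# solve M' W + W M + Q = 0 for W via Kronecker vectorization (dense,
# small systems; no dedicated Lyapunov solver is assumed available)
solve_lyapunov <- function(M, Q) {
  N <- nrow(M)
  K <- diag(N) %x% t(M) + t(M) %x% diag(N)
  matrix(solve(K, -as.numeric(Q)), N, N)
}

#' Weighted phenotypic distance to the optimum
#'
#' Evaluates the functional defined by [distance_spec()] for a system.
#' Returns `+Inf` (with attribute `divergent = TRUE`) when the horizon
#' is infinite and the weighted integral diverges.
#'
#' @param sys a `linear_system` sharing input and output dimensions with
#'   the optimum.
#' @param spec a `distance_spec`.
#' @return nonnegative scalar, possibly `+Inf`.
#' @examples
#' sp <- distance_spec(oscillator())
#' distance_to_optimum(oscillator_family(0.5), sp)  # equivalent: 0
#' @export
distance_to_optimum <- function(sys, spec) {
  stopifnot(is_linear_system(sys), inherits(spec, "distance_spec"))
  opt <- spec$optimum
  if (sys$m != opt$m || sys$l != opt$l)
    stop("system and optimum must share input and output dimensions",
         call. = FALSE)
  aug <- augmented_difference(sys, opt)
  N <- nrow(aug$A)
  Ash <- aug$A - diag(spec$sigma / 2, N)   # e^{-sigma t} folded into the state
  if (is.infinite(spec$horizon) &&
      max(Re(eigen(Ash, only.values = TRUE)$values)) >= -1e-12) {
    return(structure(Inf, divergent = TRUE))
  }
  d2 <- switch(spec$method,
    lyapunov = {
      W <- solve_lyapunov(Ash, crossprod(aug$C))
      sum(aug$B * (W %*% aug$B))
    },
    gramian = {
      # finite-horizon observability Gramian of the shifted augmented
      # system: Van Loan block exponential on a short panel, then
      # interval doubling W(2d) = W(d) + e^{A'd} W(d) e^{Ad}. The panel
      # keeps ||A|| * d small so the anti-stable block of the Van Loan
      # matrix cannot overflow at long horizons.
      Th <- spec$horizon
      k <- max(0, ceiling(log2(max(1, Th * max(abs(Ash), 1) / 0.5))))
      d <- Th / 2^k
      M <- rbind(cbind(-t(Ash), crossprod(aug$C)),
                 cbind(matrix(0, N, N), Ash))
      F0 <- expm_mat(M * d)
      E <- F0[N + seq_len(N), N + seq_len(N), drop = FALSE]  # e^{Ash d}
      W <- t(E) %*% F0[seq_len(N), N + seq_len(N), drop = FALSE]
      W <- (W + t(W)) / 2
      for (i in seq_len(k)) {
        W <- W + t(E) %*% W %*% E
        E <- E %*% E
      }
      sum(aug$B * (W %*% aug$B))
    },
    quadrature = {
      integrand <- function(ts) {
        vapply(ts, function(t) {
          hd <- aug$C %*% expm_mat(Ash * t) %*% aug$B
          sum(hd^2)
        }, 0)
      }
      stats::integrate(integrand, 0, spec$horizon,
                       rel.tol = 1e-10, abs.tol = 1e-13,
                       subdivisions = 500L)$value
    })
  sqrt(max(d2, 0))
}

#' Hybrid breakdown along a family of diverged parents
#'
#' For each \eqn{\epsilon} in `eps`, takes two homozygous parents from
#' `family` (by default the equivalent oscillators \eqn{A(0)} and
#' \eqn{A(\epsilon)}), forms the F1 (deterministic coefficient-wise
#' midpoint) and the F2 ensemble (exhaustive enumeration by default),
#' and evaluates the distance of every hybrid to the optimum. Because
#' both parents sit exactly on the equivalence set, F1 distance grows as
#' \eqn{\epsilon^2} (curvature of the set) while mean F2 distance grows
#' as \eqn{\epsilon} (segregation throws coefficients off the set by the
#' parental difference itself).
#'
#' @param eps strictly increasing vector of family parameters.
#' @param spec a `distance_spec`; default: optimum `family(0)`'s first
#'   parent, truncated horizon \eqn{40\pi} (weight \eqn{e^{-10}} at T),
#'   Gramian method.
#' @param family function of eps returning `list(p1, p2)` of
#'   `linear_system` parents; default `A(0)` vs `A(eps)` from
#'   [oscillator_family()].
#' @param design `"f2_enumerated"` (default) or `"f2_sampled"`.
#' @param weighting F2 class weights, `"mendelian"` or `"uniform"`.
#' @param n_sample number of sampled F2s when `design = "f2_sampled"`.
#' @param map_builder function building a `locus_map` from a parent
#'   system; default [locus_map_A()] (one locus per A coefficient).
#' @param seed seed used for sampled designs (recorded in the result).
#' @return a `breakdown_curve` data frame with columns `eps`,
#'   `genetic_distance`, `f1_distance`, `f2_mean_distance`,
#'   `f2_divergent_fraction`, `weighting`, `seed`.
#' @export
breakdown_curve <- function(eps,
                            spec = NULL,
                            family = function(e)
                              list(oscillator_family(0), oscillator_family(e)),
                            design = c("f2_enumerated", "f2_sampled"),
                            weighting = c("mendelian", "uniform"),
                            n_sample = 200,
                            map_builder = locus_map_A,
                            seed = 1) {
  design <- match.arg(design)
  weighting <- match.arg(weighting)
  eps <- as.numeric(eps)
  if (is.unsorted(eps, strictly = TRUE))
    stop("eps must be strictly increasing", call. = FALSE)
  if (is.null(spec))
    spec <- distance_spec(family(eps[1])[[1]], horizon = 40 * pi,
                          method = "gramian")
  st <- local_rng(seed)
  on.exit(restore_rng(st))
  rows <- lapply(eps, function(e) {
    pr <- family(e)
    map <- map_builder(pr[[1]])
    g1 <- homozygous_genotype(map, pr[[1]])
    g2 <- homozygous_genotype(map, pr[[2]])
    f1_sys <- diploid_system(diploid_genotype(map, g1$hap1, g2$hap1))
    f2 <- if (design == "f2_enumerated")
      f2_enumerate(g1, g2, weighting = weighting)
    else cross(cross(g1, g2, 1)$genotypes[[1]],
               cross(g1, g2, 1)$genotypes[[1]],
               n_offspring = n_sample, generation = "F2")
    d_f2 <- vapply(f2$systems, distance_to_optimum, 0, spec = spec)
    div <- vapply(f2$systems, is_divergent, NA, spec = spec)
    data.frame(eps = e,
               genetic_distance = genetic_distance(pr[[1]], pr[[2]]),
               f1_distance = distance_to_optimum(f1_sys, spec),
               f2_mean_distance = sum(f2$weights * d_f2),
               f2_divergent_fraction = sum(f2$weights * div),
               weighting = weighting, seed = seed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("breakdown_curve", "data.frame")
  out
}

#' Log-log scaling exponents of hybrid breakdown
#'
#' Least-squares slopes of log mean distance against log eps for F1 and
#' F2 hybrids, over a window of small eps. Slopes near 2 (F1) and 1 (F2)
#' are the numerical signature of the quadratic-vs-linear breakdown of
#' the two hybrid generations.
#'
#' @param curve a `breakdown_curve`.
#' @param window length-2 numeric, inclusive eps range used for the fit.
#' @return list with `slope_f1`, `slope_f2` and the two `lm` fits.
#' @export
scaling_exponents <- function(curve, window = range(curve$eps)) {
  stopifnot(inherits(curve, "data.frame"), length(window) == 2)
  sub <- curve[curve$eps >= window[1] & curve$eps <= window[2], ]
  if (nrow(sub) < 4)
    stop("need at least 4 grid points inside the fit window", call. = FALSE)
  if (any(!is.finite(sub$f1_distance)) || any(!is.finite(sub$f2_mean_distance)))
    stop("infinite distances inside the fit window; truncate the horizon ",
         "or shrink eps", call. = FALSE)
  if (any(sub$f1_distance <= 0) || any(sub$f2_mean_distance <= 0))
    stop("zero distances inside the fit window (identical parents?)",
         call. = FALSE)
  fit1 <- stats::lm(log(f1_distance) ~ log(eps), data = sub)
  fit2 <- stats::lm(log(f2_mean_distance) ~ log(eps), data = sub)
  list(slope_f1 = unname(stats::coef(fit1)[2]),
       slope_f2 = unname(stats::coef(fit2)[2]),
       fit_f1 = fit1, fit_f2 = fit2)
}
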