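# Neutral system drift: population-mean networks random-walking along the
# phenotypic-equivalence set, and the speed at which two isolated lineages
# accumulate hybrid incompatibility.

#' Configure a neutral drift simulation
#'
#' A population mean trait with additive genetic variance `VG` in a
#' population of effective size `Ne` moves per generation by an
#' independent normal step of variance `VG / Ne`, so after t generations
#' its displacement has variance `t * VG / Ne`. Here the "traits" are
#' coordinates on an orthonormal basis of the neutral generator algebra
#' (`VG` is interpreted per neutral direction), and each step acts on the
#' system by the exact symmetry \eqn{(A, B, C) \mapsto
#' (VAV^{-1}, VB, CV^{-1})} with \eqn{V = e^{Z}}, so every visited
#' system is exactly phenotypically equivalent to the start.
#'
#' @param VG additive genetic variance per neutral direction.
#' @param Ne effective population size.
#' @param generations number of generations to simulate.
#' @param constraint_mode constraint on the neutral directions, as in
#'   [neutral_tangent()] (default `"fixed_BC"`: only A drifts).
#' @return an object of class `drift_config`.
#' @export
drift_config <- function(VG, Ne, generations,
                         constraint_mode = c("fixed_BC", "free",
                                             "fixed_B", "fixed_C")) {
  stopifnot(VG > 0, Ne >= 1, generations >= 1)
  structure(list(VG = VG, Ne = Ne, generations = as.integer(generations),
                 constraint_mode = match.arg(constraint_mode),
                 step_sd = sqrt(VG / Ne)),
            class = "drift_config")
}

# do all generator matrices pairwise commute? (then the walk lives in an
# abelian group and e^{Z_t}...e^{Z_1} = e^{Z_1 + ... + Z_t})
generators_commute <- function(Zs, tol = 1e-12) {
  d <- length(Zs)
  if (d <= 1) return(TRUE)
  for (i in seq_len(d - 1)) for (j in seq(i + 1, d)) {
    comm <- Zs[[i]] %*% Zs[[j]] - Zs[[j]] %*% Zs[[i]]
    if (max(abs(comm)) > tol * max(1, max(abs(Zs[[i]])), max(abs(Zs[[j]]))))
      return(FALSE)
  }
  TRUE
}

# conjugate sys by V = expm(Z); in fixed-B/C modes ZB = 0 / CZ = 0 make
# VB = B and CV^{-1} = C exactly, so the step is an exact symmetry
apply_group_element <- function(sys, Z) {
  V <- expm_mat(Z)
  Vi <- expm_mat(-Z)
  make_system(V %*% sys$A %*% Vi, V %*% sys$B, sys$C %*% Vi)
}

#' Neutral random walk of a population-mean system
#'
#' Per generation, draws independent N(0, VG/Ne) coordinates on an
#' orthonormal basis of the neutral generator algebra and moves the
#' system by conjugation with the exponential of the resulting generator.
#' Because conjugation is an exact symmetry of the impulse response, the
#' walk stays exactly on the phenotypic-equivalence set (up to floating
#' point); the accumulated algebra coordinates perform an exact Gaussian
#' random walk.
#'
#' @param sys0 starting `linear_system`.
#' @param cfg a `drift_config`.
#' @param keep_systems generations at which to materialize the
#'   population-mean system (default: only the final generation; the
#'   full coordinate path is always kept, and is cheap).
#' @return a `drift_trajectory`: list with `coordinates` (generations x
#'   dimension matrix of accumulated algebra coordinates), `systems`
#'   (named list of `linear_system` at the kept generations), `basis`
#'   (the generator matrices), `sys0`, `cfg`, and `abelian` (whether the
#'   closed-form single-exponential update was usable).
#' @export
drift_walk <- function(sys0, cfg, keep_systems = cfg$generations) {
  stopifnot(is_linear_system(sys0), inherits(cfg, "drift_config"))
  nt <- neutral_tangent(sys0, cfg$constraint_mode)
  d <- nt$dimension
  if (d == 0L)
    stop("system has no neutral directions under constraint mode '",
         cfg$constraint_mode, "'", call. = FALSE)
  tgen <- cfg$generations
  steps <- matrix(stats::rnorm(tgen * d, sd = cfg$step_sd), tgen, d)
  coords <- apply(steps, 2, cumsum)
  coords <- matrix(coords, tgen, d)
  keep_systems <- sort(unique(as.integer(keep_systems)))
  stopifnot(all(keep_systems >= 1), all(keep_systems <= tgen))
  abelian <- generators_commute(nt$Z)
  systems <- vector("list", length(keep_systems))
  names(systems) <- as.character(keep_systems)
  combine <- function(coef) Reduce(`+`, Map(`*`, nt$Z, coef))
  if (abelian) {
    for (k in seq_along(keep_systems)) {
      systems[[k]] <- apply_group_element(sys0,
                                          combine(coords[keep_systems[k], ]))
    }
  } else {
    cur <- sys0
    next_keep <- 1L
    for (g in seq_len(tgen)) {
      cur <- apply_group_element(cur, combine(steps[g, ]))
      if (next_keep <= length(keep_systems) && keep_systems[next_keep] == g) {
        systems[[next_keep]] <- cur
        next_keep <- next_keep + 1L
      }
      if (next_keep > length(keep_systems)) break
    }
  }
  structure(list(coordinates = coords, systems = systems,
                 kept_generations = keep_systems,
                 basis = nt$Z, sys0 = sys0, cfg = cfg, abelian = abelian),
            class = "drift_trajectory")
}

#' @export
print.drift_trajectory <- function(x, ...) {
  cat("<drift_trajectory>", nrow(x$coordinates), "generations,",
      length(x$basis), "neutral directions,",
      length(x$systems), "systems kept\n")
  invisible(x)
}

#' Replicate algebra-coordinate walks (no system materialization)
#'
#' Simulates many independent drift lineages, tracking only the
#' accumulated algebra coordinates (each lineage is a sum of
#' per-generation normal increments). Used for checking the variance law
#' Var = t * VG / Ne and, via lineage pairs, the doubled variance of the
#' between-population difference.
#'
#' @param sys0 starting `linear_system` (fixes the tangent dimension).
#' @param cfg a `drift_config`.
#' @param at generations at which to record coordinates.
#' @param replicates number of independent lineages.
#' @return array of dimension `replicates x length(at) x dimension`.
#' @export
drift_coordinate_samples <- function(sys0, cfg, at = cfg$generations,
                                     replicates = 100) {
  stopifnot(is_linear_system(sys0), inherits(cfg, "drift_config"))
  d <- neutral_tangent(sys0, cfg$constraint_mode)$dimension
  if (d == 0L) stop("no neutral directions", call. = FALSE)
  at <- sort(unique(as.integer(at)))
  stopifnot(all(at >= 1), all(at <= cfg$generations))
  out <- array(NA_real_, dim = c(replicates, length(at), d))
  for (r in seq_len(replicates)) {
    steps <- matrix(stats::rnorm(max(at) * d, sd = cfg$step_sd), max(at), d)
    cum <- apply(steps, 2, cumsum)
    cum <- matrix(cum, max(at), d)
    out[r, , ] <- cum[at, , drop = FALSE]
  }
  out
}

#' Divergence of two isolated lineages and the fitness of their hybrids
#'
#' Evolves pairs of independent lineages from a common ancestor by
#' neutral drift, and at each checkpoint treats each lineage mean as a
#' homozygous parental population: it forms the F1 (coefficient-wise
#' midpoint) and the enumerated F2 ensemble, and evaluates hybrid
#' distances to the ancestral optimum and the quadratic fitness
#' \eqn{w = \max(0, 1 - c D^2)}. Since the between-lineage displacement
#' has variance `2 t VG / Ne` and mean F2 distance is linear in parental
#' separation, mean F2 squared distance -- and hence the fitness cost --
#' grows linearly in time: the speciation clock.
#'
#' The default genetic architecture places one locus on each A
#' coefficient ([locus_map_A()]); use `constraint_mode = "fixed_BC"`
#' (the default) so that drift moves only A.
#'
#' @param sys0 ancestral `linear_system`, assumed at the optimum.
#' @param cfg a `drift_config`.
#' @param checkpoints generations at which hybrids are formed.
#' @param spec a `distance_spec`; default: optimum `sys0`, truncated
#'   horizon \eqn{40\pi}, Gramian method.
#' @param replicates number of independent lineage pairs.
#' @param fitness_c curvature constant c of the quadratic fitness.
#' @param weighting F2 class weights, `"mendelian"` or `"uniform"`.
#' @return data frame with one row per replicate x checkpoint:
#'   `replicate`, `t`, `coord_diff_sq` (squared algebra-coordinate
#'   difference between the lineages), `genetic_distance`,
#'   `f1_distance`, `f2_mean_distance`, `f2_mean_sq_distance`,
#'   `f1_fitness`, `f2_mean_fitness`.
#' @export
divergence_experiment <- function(sys0, cfg, checkpoints,
                                  spec = NULL, replicates = 20,
                                  fitness_c = 1,
                                  weighting = c("mendelian", "uniform")) {
  stopifnot(is_linear_system(sys0), inherits(cfg, "drift_config"))
  weighting <- match.arg(weighting)
  checkpoints <- sort(unique(as.integer(checkpoints)))
  stopifnot(all(checkpoints >= 1), all(checkpoints <= cfg$generations))
  if (is.null(spec))
    spec <- distance_spec(sys0, horizon = 40 * pi, method = "gramian")
  map <- locus_map_A(sys0)
  wfit <- function(d) pmax(0, 1 - fitness_c * d^2)
  rows <- vector("list", replicates * length(checkpoints))
  idx <- 1L
  for (r in seq_len(replicates)) {
    w1 <- drift_walk(sys0, cfg, keep_systems = checkpoints)
    w2 <- drift_walk(sys0, cfg, keep_systems = checkpoints)
    for (k in seq_along(checkpoints)) {
      tg <- checkpoints[k]
      s1 <- w1$systems[[as.character(tg)]]
      s2 <- w2$systems[[as.character(tg)]]
      g1 <- homozygous_genotype(map, s1)
      g2 <- homozygous_genotype(map, s2)
      f1_sys <- diploid_system(diploid_genotype(map, g1$hap1, g2$hap1))
      f2 <- f2_enumerate(g1, g2, weighting = weighting)
      d_f2 <- vapply(f2$systems, distance_to_optimum, 0, spec = spec)
      d_f1 <- distance_to_optimum(f1_sys, spec)
      cd <- w1$coordinates[tg, ] - w2$coordinates[tg, ]
      rows[[idx]] <- data.frame(
        replicate = r, t = tg,
        coord_diff_sq = sum(cd^2),
        genetic_distance = genetic_distance(s1, s2),
        f1_distance = d_f1,
        f2_mean_distance = sum(f2$weights * d_f2),
        f2_mean_sq_distance = sum(f2$weights * d_f2^2),
        f1_fitness = wfit(d_f1),
        f2_mean_fitness = sum(f2$weights * wfit(d_f2)))
      idx <- idx + 1L
    }
  }
  do.call(rbind, rows)
}
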