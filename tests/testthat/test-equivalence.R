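test_that("reachable and unobservable subspaces match their definitions", {
  osc <- oscillator()
  expect_equal(ncol(reachable_subspace(osc)), 2)       # [B, AB] full rank
  expect_equal(ncol(unobservable_subspace(osc)), 0)    # [C; CA] full rank

  nob <- make_system(osc$A, matrix(0, 2, 1), osc$C)
  expect_equal(ncol(reachable_subspace(nob)), 0)
  blind <- make_system(osc$A, osc$B, matrix(0, 1, 2))
  expect_equal(ncol(unobservable_subspace(blind)), 2)

  # block-diagonal system with B supported on the first block
  A <- as.matrix(Matrix::bdiag(matrix(c(0, -1, 1, 0), 2, 2),
                               matrix(-0.5)))
  sys <- make_system(A, c(1, 1, 0), t(c(1, 0, 1)))
  R <- reachable_subspace(sys)
  expect_equal(ncol(R), 2)
  expect_lt(max(abs(R[3, ])), 1e-12)

  # returned unobservable basis U satisfies A U in span(U) and C U = 0
  set.seed(8)
  padded <- pad_nonminimal(oscillator(), 2, c("ro_bar", "rbar_obar"),
                           seed = 5)
  U <- unobservable_subspace(padded)
  expect_equal(ncol(U), 2)
  expect_lt(max(abs(padded$C %*% U)), 1e-8)
  proj <- U %*% (t(U) %*% (padded$A %*% U))
  expect_lt(max(abs(padded$A %*% U - proj)), 1e-8)
})

test_that("the Kalman decomposition exhibits the block zero pattern", {
  osc <- oscillator()
  kd <- kalman_decomposition(osc)
  expect_equal(unname(kd$dims), c(0, 2, 0, 0))
  expect_true(phenotypically_equivalent(kd$minimal, osc))

  # padding with one dimension of each silent class
  for (seed in 1:10) {
    p <- pad_nonminimal(osc, 3, c("ro_bar", "rbar_obar", "rbar_o"),
                        seed = seed)
    kd <- kalman_decomposition(p)
    expect_equal(unname(kd$dims), c(1, 2, 1, 1))
    d <- kd$dims
    At <- kd$transformed$A
    scale_A <- max(abs(At))
    blocks <- function(i) switch(i,
      seq_len(d[1]),
      d[1] + seq_len(d[2]),
      d[1] + d[2] + seq_len(d[3]),
      d[1] + d[2] + d[3] + seq_len(d[4]))
    for (zero in list(c(2, 1), c(3, 1), c(4, 1), c(3, 2), c(4, 2),
                      c(2, 3), c(4, 3))) {
      blk <- At[blocks(zero[1]), blocks(zero[2]), drop = FALSE]
      if (length(blk))
        expect_lt(max(abs(blk)), 1e-8 * scale_A)
    }
    # B supported on reachable blocks, C on observable blocks
    expect_lt(max(abs(kd$transformed$B[c(blocks(3), blocks(4)), ])), 1e-8)
    expect_lt(max(abs(kd$transformed$C[, c(blocks(1), blocks(3))])), 1e-8)
    expect_true(phenotypically_equivalent(kd$minimal, osc, tol = 1e-6))
  }

  # a blind system has no reachable-observable part and zero response
  blind <- make_system(matrix(c(0, -1, 1, 0), 2, 2), c(1, 1),
                       matrix(0, 1, 2))
  kdb <- kalman_decomposition(blind)
  expect_equal(kdb$dims[["ro"]], 0)
  h <- impulse_response(kdb$minimal, c(0, 1, 2))
  expect_equal(max(abs(h$values)), 0)
})

test_that("minimal realization dimension equals the block-Hankel rank", {
  osc <- oscillator()
  set.seed(77)
  for (seed in 1:25) {
    n_extra <- sample(1:3, 1)
    cls <- sample(c("ro_bar", "rbar_obar", "rbar_o"), n_extra,
                  replace = TRUE)
    p <- pad_nonminimal(osc, n_extra, cls, seed = seed)
    mr <- minimal_realization(p)
    expect_equal(mr$n, 2)
    expect_equal(hankel_rank(p), 2)
    expect_true(phenotypically_equivalent(mr, osc, tol = 1e-6))
  }
  # already-minimal random systems keep their dimension
  for (seed in 1:5) {
    sys <- random_system(3, 1, 1, seed = seed)
    expect_equal(minimal_realization(sys)$n, hankel_rank(sys))
    expect_equal(hankel_rank(sys), 3)
  }
})

test_that("padding never changes the impulse response", {
  osc <- oscillator()
  set.seed(101)
  for (rep in 1:20) {
    n_extra <- sample(1:3, 1)
    cls <- sample(c("ro_bar", "rbar_obar", "rbar_o"), n_extra,
                  replace = TRUE)
    p <- pad_nonminimal(osc, n_extra, cls, seed = rep + 200)
    expect_true(phenotypically_equivalent(p, osc, tol = 1e-6))
  }
})

test_that("neutral tangent dimensions: oscillator degeneracy and generic count", {
  osc <- oscillator()
  nt <- neutral_tangent(osc, "fixed_BC")
  expect_equal(nt$dimension, 1)
  # generator proportional to [[0,0],[1,-1]] (the Example-2 direction)
  Z <- nt$Z[[1]] / nt$Z[[1]][2, 1]
  expect_equal(Z, matrix(c(0, 1, 0, -1), 2, 2), tolerance = 1e-10)
  expect_lt(max(abs(Z %*% osc$B)), 1e-12)
  expect_lt(max(abs(osc$C %*% Z)), 1e-12)

  # free mode spans all n^2 generators; Z = I commutes with A, so the
  # identity direction moves only B and C: (0, B, -C)
  ntf <- neutral_tangent(osc, "free")
  expect_equal(ntf$dimension, 4)
  id_dir <- list(dA = diag(2) %*% osc$A - osc$A %*% diag(2),
                 dB = diag(2) %*% osc$B, dC = -osc$C %*% diag(2))
  expect_equal(id_dir$dA, matrix(0, 2, 2))
  expect_equal(id_dir$dB, osc$B)
  expect_equal(id_dir$dC, -osc$C)
  stepped <- tangent_step(osc, id_dir, 0.05)
  expect_true(phenotypically_equivalent(stepped, osc, tol = 1e-2))

  # generic systems: computed dimension is (n - l)(n - m); the naive
  # count n(n - l - m) treats the l*m overlapping constraints CZB = 0
  # as if they were imposed twice, and already fails for the oscillator
  # (computed 1, naive 0)
  for (cfg in list(c(4, 1, 1), c(5, 2, 1), c(6, 1, 2))) {
    sys <- random_system(cfg[1], cfg[2], cfg[3], seed = sum(cfg))
    nt <- neutral_tangent(sys, "fixed_BC")
    expect_equal(nt$dimension, (cfg[1] - cfg[3]) * (cfg[1] - cfg[2]))
    expect_equal(nt$generic_dimension, cfg[1] * (cfg[1] - cfg[3] - cfg[2]))
    for (g in nt$generators[seq_len(2)]) {
      expect_lt(max(abs(g$dB)), 1e-9)
      expect_lt(max(abs(g$dC)), 1e-9)
    }
  }
})

test_that("tangent steps are first-order neutral: distance scales as eps^2", {
  osc <- oscillator()
  spec <- distance_spec(osc, method = "lyapunov")
  eps <- c(1e-2, 1e-3, 1e-4)
  # oscillator fixed-B,C generator
  gen <- neutral_tangent(osc, "fixed_BC")$generators[[1]]
  d <- vapply(eps, function(e)
    distance_to_optimum(tangent_step(osc, gen, e), spec), 0)
  slope <- stats::coef(stats::lm(log(d) ~ log(eps)))[2]
  expect_equal(unname(slope), 2, tolerance = 0.1)

  # free-mode generators of a stable random system (B and C move too);
  # steps large enough that D^2 stays above quadratic-form roundoff
  sys <- random_system(3, 1, 1, seed = 21, spectral_bound = -0.3)
  spec2 <- distance_spec(sys, method = "lyapunov")
  nt <- neutral_tangent(sys, "free")
  eps2 <- c(1e-2, 3e-3, 1e-3)
  set.seed(1)
  for (g in nt$generators[sample(length(nt$generators), 3)]) {
    d <- vapply(eps2, function(e)
      distance_to_optimum(tangent_step(sys, g, e), spec2), 0)
    if (max(d) < 1e-12) next  # generator in the stabilizer: exactly neutral
    slope <- stats::coef(stats::lm(log(d) ~ log(eps2)))[2]
    expect_equal(unname(slope), 2, tolerance = 0.1)
  }
})
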