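make_parents <- function(eps, x_columns = integer(0)) {
  p1 <- oscillator_family(0)
  p2 <- oscillator_family(eps)
  map <- locus_map_A(p1, x_columns = x_columns)
  list(map = map,
       g1 = homozygous_genotype(map, p1),
       g2 = homozygous_genotype(map, p2),
       p1 = p1, p2 = p2)
}

test_that("locus maps validate addresses and disjointness", {
  osc <- oscillator()
  expect_error(locus_map(data.frame(locus = "x", mat = "A", row = 3, col = 1),
                         osc), "out of bounds")
  dup <- data.frame(locus = c("x", "y"), mat = "A", row = 1, col = 1)
  expect_error(locus_map(dup, osc), "disjoint")
  m <- locus_map_A(osc, x_columns = 2)
  expect_equal(sum(m$chromosome == "X"), 2)
  expect_equal(length(m$locus_ids), 4)
})

test_that("diploid systems average haplotypes; the A(0) x A(-2) F1 runs away", {
  pr <- make_parents(-2)
  # homozygote reproduces its own system exactly
  expect_system_equal(diploid_system(pr$g1), pr$p1)

  f1 <- diploid_system(diploid_genotype(pr$map, pr$g1$hap1, pr$g2$hap1))
  expect_equal(f1$A, matrix(c(1, 2, 0, -1), 2, 2))
  # its phenotype is e^t: exponential runaway instead of oscillation
  ts <- seq(0, 3, length.out = 60)
  h <- drop(impulse_response(f1, ts)$values)
  expect_lt(max(abs(h - exp(ts)) / exp(ts)), 1e-8)
})

test_that("meiosis segregates unlinked loci independently and reproducibly", {
  pr <- make_parents(0.5)
  # homozygote gametes are the parental haplotype
  expect_identical(gamete(pr$g1), pr$g1$hap1)

  het <- diploid_genotype(pr$map, pr$g1$hap1, pr$g2$hap1)
  set.seed(11)
  g_a <- gamete(het)
  set.seed(11)
  expect_identical(gamete(het), g_a)

  # per-locus allele frequencies 1/2, joint classes uniform over 16
  set.seed(99)
  n_draw <- 4000
  draws <- replicate(n_draw, gamete(het))
  from1 <- draws == pr$g1$hap1   # 4 addresses x draws logical
  freq <- rowMeans(from1)
  expect_true(all(abs(freq - 0.5) < 4 * sqrt(0.25 / n_draw)))
  class_id <- apply(from1, 2, function(z) sum(z * 2^(0:3)))
  tab <- tabulate(class_id + 1, 16)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("crosses follow Mendelian ratios and fix homozygotes", {
  pr <- make_parents(0.5)
  set.seed(3)
  f1s <- cross(pr$g1, pr$g2, n_offspring = 5)
  # all F1s of homozygous parents are the identical heterozygote
  for (g in f1s$genotypes) {
    expect_identical(g$hap1, pr$g1$hap1)
    expect_identical(g$hap2, pr$g2$hap1)
  }
  # selfing a homozygote returns the parent
  selfed <- cross(pr$g1, pr$g1, n_offspring = 2)
  expect_system_equal(selfed$systems[[1]], pr$p1)

  # F2 per-locus genotype frequencies 1/4, 1/2, 1/4
  set.seed(17)
  f1 <- f1s$genotypes[[1]]
  n_draw <- 4000
  locus1_state <- replicate(n_draw, {
    off <- diploid_genotype(pr$map, gamete(f1), gamete(f1))
    a <- c(off$hap1[1], off$hap2[1])
    sum(a == pr$g2$hap1[1])   # 0, 1, 2 copies of the p2 allele
  })
  counts <- tabulate(locus1_state + 1, 3)
  expect_gt(stats::chisq.test(counts, p = c(.25, .5, .25))$p.value, 1e-4)
})

test_that("F2 enumeration covers all 3^L classes with conserved means", {
  pr <- make_parents(0.5)
  f2 <- f2_enumerate(pr$g1, pr$g2)
  expect_equal(length(f2$systems), 81)
  expect_equal(ncol(f2$states), 81)
  expect_equal(sum(f2$weights_mendelian), 1, tolerance = 1e-12)
  expect_equal(sum(f2$weights_uniform), 1, tolerance = 1e-12)

  # Mendelian-weighted mean coefficients equal the F1 midpoint
  f1 <- diploid_system(diploid_genotype(pr$map, pr$g1$hap1, pr$g2$hap1))
  meanA <- Reduce(`+`, Map(function(s, w) w * s$A,
                           f2$systems, f2$weights_mendelian))
  expect_equal(meanA, f1$A, tolerance = 1e-12)

  # every F2 coefficient lies between the parental values
  lo <- pmin(pr$p1$A, pr$p2$A); hi <- pmax(pr$p1$A, pr$p2$A)
  for (s in f2$systems) {
    expect_true(all(s$A >= lo - 1e-12 & s$A <= hi + 1e-12))
  }

  # single locus: 3 genotypes with weights 1/4, 1/2, 1/4
  m1 <- locus_map(data.frame(locus = "a", mat = "A", row = 1, col = 1),
                  pr$p1)
  f2_1 <- f2_enumerate(homozygous_genotype(m1, pr$p1),
                       homozygous_genotype(m1, pr$p2))
  expect_equal(length(f2_1$systems), 3)
  expect_equal(sort(f2_1$weights_mendelian), c(0.25, 0.25, 0.5))

  # identical parents collapse to identical systems
  f2_same <- f2_enumerate(pr$g1, pr$g1)
  for (s in f2_same$systems) expect_system_equal(s, pr$p1)

  het <- diploid_genotype(pr$map, pr$g1$hap1, pr$g2$hap1)
  expect_error(f2_enumerate(het, pr$g1), "homozygous")
})

test_that("the X-linked F1 male mixes averaged autosomes with maternal X", {
  eps <- -2
  pr <- make_parents(eps, x_columns = 2)
  # father homozygous A(0), mother homozygous A(-2); column 2 on the X
  son <- haldane_f1(pr$g1, pr$g2, sex = "male")
  son_sys <- diploid_system(son, dosage = 2)
  A0 <- pr$p1$A; Am <- pr$p2$A
  expected <- cbind((A0[, 1] + Am[, 1]) / 2, Am[, 2])
  expect_equal(son_sys$A, expected, tolerance = 1e-12)

  # daughter equals the all-autosomal F1 average
  daughter <- haldane_f1(pr$g1, pr$g2, sex = "female")
  expect_equal(diploid_system(daughter)$A, (A0 + Am) / 2, tolerance = 1e-12)

  # the son's coefficient pattern is a member of the autosomal F2
  # enumeration: heterozygous at autosomal loci, maternal-homozygous at
  # X loci
  pr_aut <- make_parents(eps)
  f2 <- f2_enumerate(pr_aut$g1, pr_aut$g2)
  hits <- vapply(f2$systems, function(s) max(abs(s$A - son_sys$A)) < 1e-12,
                 NA)
  expect_equal(sum(hits), 1)

  # dosage factor scales the hemizygous contribution
  son_d1 <- diploid_system(son, dosage = 1)
  expect_equal(son_d1$A[, 2], Am[, 2] / 2, tolerance = 1e-12)

  expect_error(haldane_f1(pr_aut$g1, pr_aut$g2, sex = "male"),
               "no X-linked loci")
})

test_that("with all loci autosomal the F1 sexes coincide with the standard F1", {
  pr <- make_parents(0.4)
  f1 <- diploid_system(diploid_genotype(pr$map, pr$g1$hap1, pr$g2$hap1))
  # both sexes via plain cross: deterministic for homozygous parents
  off <- cross(pr$g1, pr$g2, n_offspring = 1)
  expect_system_equal(off$systems[[1]], f1)
})

test_that("genetic distance is the Frobenius distance between A matrices", {
  a0 <- oscillator_family(0)
  am2 <- oscillator_family(-2)
  expect_equal(genetic_distance(a0, a0), 0)
  expect_equal(genetic_distance(a0, am2), sqrt(48), tolerance = 1e-12)
  expect_equal(genetic_distance(a0, am2), genetic_distance(am2, a0))
  b <- make_system(a0$A, 2 * a0$B, a0$C)
  expect_equal(genetic_distance(a0, b), 0)
  expect_equal(genetic_distance(a0, b, include_BC = TRUE), sqrt(2))
  expect_error(genetic_distance(a0, random_system(3, 1, 1, seed = 1)),
               "equal dimensions")
})
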