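# Diploid genetics over system coefficients: unlinked nonrecombining loci,
# meiosis, F1/F2 hybrid construction (sampled and exhaustively enumerated),
# and the X-linked architecture behind Haldane's rule.

#' Genetic architecture over system coefficients
#'
#' A locus map assigns coefficients of (A, B, C) to unlinked,
#' nonrecombining loci, each on an autosome or on the X chromosome. A
#' locus may own several coefficient addresses (e.g. a whole promoter row
#' of A, inherited together in cis); coefficients not owned by any locus
#' are genetically invariant and taken from `base`.
#'
#' @param loci data frame with columns `locus` (identifier), `mat` (one
#'   of `"A"`, `"B"`, `"C"`), `row`, `col` (1-based coefficient address)
#'   and optionally `chromosome` (`"autosome"` or `"X"`, default
#'   autosome).
#' @param base a `linear_system` supplying dimensions and the invariant
#'   coefficients.
#' @return an object of class `locus_map`.
#' @seealso [locus_map_A()] for the default one-locus-per-A-coefficient
#'   architecture.
#' @export
locus_map <- function(loci, base) {
  stopifnot(is.data.frame(loci), is_linear_system(base))
  req <- c("locus", "mat", "row", "col")
  if (!all(req %in% names(loci)))
    stop("loci must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (nrow(loci) == 0L)
    stop("locus map must contain at least one locus", call. = FALSE)
  if (is.null(loci$chromosome)) loci$chromosome <- "autosome"
  if (!all(loci$mat %in% c("A", "B", "C")))
    stop("mat must be one of A, B, C", call. = FALSE)
  if (!all(loci$chromosome %in% c("autosome", "X")))
    stop("chromosome must be 'autosome' or 'X'", call. = FALSE)
  dims <- list(A = c(base$n, base$n), B = c(base$n, base$m),
               C = c(base$l, base$n))
  for (i in seq_len(nrow(loci))) {
    d <- dims[[loci$mat[i]]]
    if (loci$row[i] < 1 || loci$row[i] > d[1] ||
        loci$col[i] < 1 || loci$col[i] > d[2])
      stop("address ", loci$mat[i], "[", loci$row[i], ",", loci$col[i],
           "] out of bounds", call. = FALSE)
  }
  key <- paste(loci$mat, loci$row, loci$col)
  if (anyDuplicated(key))
    stop("coefficient addresses must be disjoint across loci; duplicated: ",
         key[duplicated(key)][1], call. = FALSE)
  chr_by_locus <- tapply(loci$chromosome, loci$locus, function(x) {
    if (length(unique(x)) > 1)
      stop("a locus cannot span chromosomes", call. = FALSE)
    x[1]
  })
  loci$locus <- as.character(loci$locus)
  structure(list(addresses = loci[, c("locus", "mat", "row", "col",
                                      "chromosome")],
                 locus_ids = names(chr_by_locus),
                 chromosome = as.character(chr_by_locus),
                 base = base),
            class = "locus_map")
}

#' @export
print.locus_map <- function(x, ...) {
  cat("<locus_map>", length(x$locus_ids), "loci over",
      nrow(x$addresses), "coefficient addresses (",
      sum(x$chromosome == "X"), "X-linked )\n")
  invisible(x)
}

#' One unlinked locus per regulatory coefficient
#'
#' The default architecture: each entry of A is encoded by its own
#' nonrecombining, unlinked locus, with B and C genetically invariant.
#' Columns of A listed in `x_columns` are placed on the X chromosome
#' (all coefficients of the corresponding regulator); everything else is
#' autosomal.
#'
#' @param base a `linear_system` supplying dimensions and the invariant
#'   B and C.
#' @param x_columns integer vector of A columns to place on the X
#'   chromosome (default none).
#' @return a `locus_map`.
#' @export
locus_map_A <- function(base, x_columns = integer(0)) {
  stopifnot(is_linear_system(base))
  idx <- expand.grid(row = seq_len(base$n), col = seq_len(base$n))
  loci <- data.frame(locus = paste0("A", idx$row, idx$col),
                     mat = "A", row = idx$row, col = idx$col,
                     chromosome = ifelse(idx$col %in% x_columns,
                                         "X", "autosome"))
  locus_map(loci, base)
}

#' Extract the varying coefficient values of a system as a haplotype
#'
#' @param map a `locus_map`.
#' @param sys a `linear_system` with the same dimensions as `map$base`.
#' @return numeric vector, one allele value per coefficient address (in
#'   map order).
#' @export
haplotype_values <- function(map, sys) {
  stopifnot(inherits(map, "locus_map"), is_linear_system(sys))
  if (sys$n != map$base$n || sys$m != map$base$m || sys$l != map$base$l)
    stop("system dimensions do not match the locus map", call. = FALSE)
  ad <- map$addresses
  vapply(seq_len(nrow(ad)),
         function(i) sys[[ad$mat[i]]][ad$row[i], ad$col[i]],
         0)
}

# assemble a linear_system from per-address coefficient values
system_from_values <- function(map, values) {
  ad <- map$addresses
  A <- map$base$A; B <- map$base$B; C <- map$base$C
  for (i in seq_len(nrow(ad))) {
    switch(ad$mat[i],
           A = A[ad$row[i], ad$col[i]] <- values[i],
           B = B[ad$row[i], ad$col[i]] <- values[i],
           C = C[ad$row[i], ad$col[i]] <- values[i])
  }
  make_system(A, B, C)
}

#' Construct a diploid genotype
#'
#' A diploid carries two haplotypes over the shared locus map. Males are
#' hemizygous at X-linked loci: their second haplotype carries no X
#' alleles (`NA`), and by convention haplotype 1 is the maternally
#' inherited one.
#'
#' @param map a `locus_map`.
#' @param hap1,hap2 numeric vectors of allele values (one per coefficient
#'   address), or `linear_system` objects from which the values are
#'   extracted.
#' @param sex `"female"`, `"male"` or `"unsexed"`.
#' @return an object of class `diploid_genotype`.
#' @export
diploid_genotype <- function(map, hap1, hap2, sex = c("unsexed", "female",
                                                      "male")) {
  stopifnot(inherits(map, "locus_map"))
  sex <- match.arg(sex)
  if (is_linear_system(hap1)) hap1 <- haplotype_values(map, hap1)
  if (is_linear_system(hap2)) hap2 <- haplotype_values(map, hap2)
  nad <- nrow(map$addresses)
  stopifnot(length(hap1) == nad, length(hap2) == nad)
  x_addr <- map$addresses$chromosome == "X"
  if (sex == "male") {
    hap2[x_addr] <- NA_real_
  }
  if (any(!is.finite(hap1)) ||
      any(!is.finite(hap2[if (sex == "male") !x_addr else TRUE])))
    stop("haplotype values must be finite", call. = FALSE)
  structure(list(map = map, hap1 = hap1, hap2 = hap2, sex = sex),
            class = "diploid_genotype")
}

#' @export
print.diploid_genotype <- function(x, ...) {
  cat("<diploid_genotype>", x$sex, "over",
      length(x$map$locus_ids), "loci\n")
  invisible(x)
}

#' Homozygous genotype carrying a given system on both haplotypes
#'
#' @inheritParams diploid_genotype
#' @param sys a `linear_system`.
#' @export
homozygous_genotype <- function(map, sys, sex = "unsexed") {
  v <- haplotype_values(map, sys)
  diploid_genotype(map, v, v, sex)
}

is_homozygous <- function(g) {
  ok <- !is.na(g$hap2)
  all(g$hap1[ok] == g$hap2[ok])
}

#' Phenotype-determining system of a diploid
#'
#' A diploid that inherited systems (A', B', C') and (A'', B'', C'') has
#' its phenotype determined by the coefficient-wise average
#' ((A'+A'')/2, (B'+B'')/2, (C'+C'')/2). For a male's hemizygous X-linked
#' coefficients the single maternal allele contributes with multiplier
#' `dosage / 2`; the default `dosage = 2` models full dosage
#' compensation (the single X upregulated twofold, as in *Drosophila*),
#' so a hemizygous allele contributes like a homozygote.
#'
#' @param g a `diploid_genotype`.
#' @param dosage dosage-compensation factor for hemizygous X alleles.
#' @return a `linear_system`.
#' @export
diploid_system <- function(g, dosage = 2) {
  stopifnot(inherits(g, "diploid_genotype"))
  vals <- (g$hap1 + g$hap2) / 2
  hemi <- is.na(g$hap2)
  if (any(hemi)) {
    if (g$sex != "male")
      stop("missing second allele in a non-male genotype", call. = FALSE)
    if (is.null(dosage) || !is.finite(dosage))
      stop("male genotype with X-linked loci requires a dosage factor",
           call. = FALSE)
    vals[hemi] <- (dosage / 2) * g$hap1[hemi]
  }
  system_from_values(g$map, vals)
}

#' Draw a gamete by meiosis
#'
#' Each locus independently transmits one of its two alleles with
#' probability 1/2 (all addresses of a multi-coefficient locus travel
#' together; loci are unlinked). Hemizygous X loci of a male transmit the
#' single allele (segregation to daughters vs sons is handled by the
#' cross functions). Uses R's global random number generator; call
#' `set.seed()` for reproducibility.
#'
#' @param g a `diploid_genotype`.
#' @return numeric vector of allele values, one per coefficient address.
#' @export
gamete <- function(g) {
  stopifnot(inherits(g, "diploid_genotype"))
  map <- g$map
  pick <- stats::runif(length(map$locus_ids)) < 0.5
  names(pick) <- map$locus_ids
  from1 <- pick[map$addresses$locus]
  out <- unname(ifelse(from1, g$hap1, g$hap2))
  hemi <- is.na(out)
  out[hemi] <- g$hap1[hemi]   # male X: only the single allele can transmit
  out
}

#' Cross two diploids
#'
#' Each offspring receives one independently drawn gamete from each
#' parent. An F1 is an offspring of two (typically homozygous) parental
#' populations; an F2 is an offspring of two independently formed F1s,
#' obtained by calling `cross` on the F1s.
#'
#' @param p1,p2 `diploid_genotype` objects sharing a locus map.
#' @param n_offspring number of offspring to draw.
#' @param generation label stored in the result (e.g. `"F1"`, `"F2"`).
#' @param dosage passed to [diploid_system()].
#' @return a `hybrid_ensemble` with equal weights.
#' @export
cross <- function(p1, p2, n_offspring = 1, generation = "F1", dosage = 2) {
  stopifnot(inherits(p1, "diploid_genotype"), inherits(p2, "diploid_genotype"))
  if (!identical(p1$map$addresses, p2$map$addresses))
    stop("parents must share a locus map", call. = FALSE)
  genotypes <- vector("list", n_offspring)
  systems <- vector("list", n_offspring)
  for (k in seq_len(n_offspring)) {
    g <- diploid_genotype(p1$map, gamete(p1), gamete(p2))
    genotypes[[k]] <- g
    systems[[k]] <- diploid_system(g, dosage)
  }
  hybrid_ensemble(genotypes, systems,
                  weights = rep(1 / n_offspring, n_offspring),
                  generation = generation)
}

hybrid_ensemble <- function(genotypes, systems, weights, generation,
                            states = NULL, weights_mendelian = NULL,
                            weights_uniform = NULL) {
  stopifnot(length(systems) == length(weights),
            abs(sum(weights) - 1) <= 1e-12)
  structure(list(genotypes = genotypes, systems = systems,
                 weights = weights, generation = generation,
                 states = states,
                 weights_mendelian = weights_mendelian,
                 weights_uniform = weights_uniform),
            class = "hybrid_ensemble")
}

#' @export
print.hybrid_ensemble <- function(x, ...) {
  cat("<hybrid_ensemble>", x$generation, "with", length(x$systems),
      "genotypes\n")
  invisible(x)
}

#' Exhaustively enumerate F2 hybrids of two homozygous parents
#'
#' With L unlinked biallelic loci every F2 genotype is a choice, per
#' locus, of homozygous-parent-1, heterozygous, or homozygous-parent-2,
#' giving all \eqn{3^L} combinations (81 for the four A coefficients of
#' the two-gene oscillator). Mendelian weights multiply (1/4, 1/2, 1/4)
#' across loci; a uniform weighting over the \eqn{3^L} classes is stored
#' alongside. The `weights` element follows `weighting`.
#'
#' @param p1,p2 homozygous `diploid_genotype` objects sharing a locus
#'   map.
#' @param weighting `"mendelian"` (default) or `"uniform"`.
#' @param dosage passed to [diploid_system()].
#' @param max_genotypes refuse to enumerate more than this many
#'   (default `3^12`); use [cross()] to sample instead.
#' @return a `hybrid_ensemble`; its `states` element is an L x 3^L
#'   integer matrix with entries 0 (homozygous p1), 1 (heterozygous),
#'   2 (homozygous p2).
#' @export
f2_enumerate <- function(p1, p2, weighting = c("mendelian", "uniform"),
                         dosage = 2, max_genotypes = 3^12) {
  stopifnot(inherits(p1, "diploid_genotype"), inherits(p2, "diploid_genotype"))
  weighting <- match.arg(weighting)
  if (!identical(p1$map$addresses, p2$map$addresses))
    stop("parents must share a locus map", call. = FALSE)
  if (!is_homozygous(p1) || !is_homozygous(p2))
    stop("f2_enumerate requires homozygous parents; use cross() to sample F2s of heterozygotes",
         call. = FALSE)
  map <- p1$map
  L <- length(map$locus_ids)
  if (3^L > max_genotypes)
    stop("3^", L, " genotypes exceed the enumeration cap (", max_genotypes,
         "); sample F2s with cross() instead", call. = FALSE)
  states <- as.matrix(expand.grid(rep(list(0:2), L)))  # 3^L x L
  states <- t(states)                                  # L x 3^L
  dimnames(states) <- list(map$locus_ids, NULL)
  wm <- apply(states, 2, function(s) prod(c(0.25, 0.5, 0.25)[s + 1]))
  wu <- rep(1 / ncol(states), ncol(states))
  locus_of <- match(map$addresses$locus, map$locus_ids)
  genotypes <- vector("list", ncol(states))
  systems <- vector("list", ncol(states))
  for (k in seq_len(ncol(states))) {
    s <- states[, k][locus_of]                    # per-address state
    h1 <- ifelse(s == 2, p2$hap1, p1$hap1)        # state 0/1 -> p1 allele
    h2 <- ifelse(s == 0, p1$hap1, p2$hap1)        # state 1/2 -> p2 allele
    g <- diploid_genotype(map, h1, h2)
    genotypes[[k]] <- g
    systems[[k]] <- diploid_system(g, dosage)
  }
  hybrid_ensemble(genotypes, systems,
                  weights = if (weighting == "mendelian") wm else wu,
                  generation = "F2", states = states,
                  weights_mendelian = wm, weights_uniform = wu)
}

#' F1 offspring with X-linked loci: the Haldane's rule construction
#'
#' In an XY system, an F1 daughter receives an X from each parent, so at
#' X-linked loci she is an ordinary heterozygote; an F1 son receives his
#' single X from his mother only and is hemizygous there, with the
#' maternal allele amplified by dosage compensation. His system
#' coefficients therefore mix averaged autosomal entries with purely
#' maternal X entries -- a combination that, for all-autosomal
#' inheritance, could arise only in an F2. Heterogametic F1s thus show
#' F2-like phenotypic variation, which is the model's account of
#' Haldane's rule.
#'
#' @param father,mother `diploid_genotype` objects sharing a locus map
#'   that contains at least one X-linked locus. Gametes are drawn by
#'   meiosis (deterministic for homozygous parents).
#' @param sex sex of the offspring, `"male"` or `"female"`.
#' @param dosage dosage-compensation factor (default 2).
#' @return a `diploid_genotype` of the requested sex (haplotype 1
#'   maternal).
#' @export
haldane_f1 <- function(father, mother, sex = c("male", "female"),
                       dosage = 2) {
  stopifnot(inherits(father, "diploid_genotype"),
            inherits(mother, "diploid_genotype"))
  sex <- match.arg(sex)
  if (!identical(father$map$addresses, mother$map$addresses))
    stop("parents must share a locus map", call. = FALSE)
  map <- mother$map
  if (!any(map$chromosome == "X"))
    stop("locus map has no X-linked loci; use cross() for an autosomal F1",
         call. = FALSE)
  maternal <- gamete(mother)
  paternal <- gamete(father)
  diploid_genotype(map, maternal, paternal, sex)
}

#' Genetic distance between two systems
#'
#' Frobenius distance between regulatory matrices:
#' \eqn{(\sum_{ij} (A_{ij} - \bar A_{ij})^2)^{1/2}}. Differences in B
#' and C are included only when `include_BC = TRUE`.
#'
#' @param s1,s2 `linear_system` objects of equal dimensions.
#' @param include_BC also accumulate squared differences of B and C.
#' @return nonnegative scalar.
#' @examples
#' genetic_distance(oscillator_family(0), oscillator_family(-2))  # sqrt(48)
#' @export
genetic_distance <- function(s1, s2, include_BC = FALSE) {
  stopifnot(is_linear_system(s1), is_linear_system(s2))
  if (s1$n != s2$n || s1$m != s2$m || s1$l != s2$l)
    stop("systems must have equal dimensions", call. = FALSE)
  d2 <- sum((s1$A - s2$A)^2)
  if (include_BC) d2 <- d2 + sum((s1$B - s2$B)^2) + sum((s1$C - s2$C)^2)
  sqrt(d2)
}
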