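# Plain-text system files and deterministic figure-reproduction recipes.

#' Write a linear system to a plain-text file
#'
#' The format holds labelled blocks `A:`, `B:`, `C:`, one matrix row per
#' line, entries separated by whitespace, written at 17 significant
#' digits so that write/read round-trips are bit-stable.
#'
#' @param sys a `linear_system`.
#' @param path output file path.
#' @export
write_system <- function(sys, path) {
  stopifnot(is_linear_system(sys))
  fmt <- function(M) apply(M, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  lines <- c("A:", fmt(sys$A), "B:", fmt(sys$B), "C:", fmt(sys$C))
  writeLines(lines, path)
  invisible(path)
}

#' Read a linear system from a plain-text file
#'
#' Accepts two dialects: the labelled-block format written by
#' [write_system()] (blocks introduced by `A:`, `B:`, `C:` in any
#' order), and an unlabelled delimited format of three matrices
#' separated by blank lines, in the order A, B, C. Entries may be
#' separated by whitespace or commas; lines starting with `#` are
#' comments. Parse errors report the offending line number.
#'
#' @param path input file path.
#' @return a `linear_system`.
#' @export
read_system <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw)
  lines <- raw
  lines[!keep] <- ""
  labelled <- any(grepl("^\\s*[ABC]\\s*:\\s*$", lines))
  parse_row <- function(i) {
    txt <- gsub(",", " ", lines[i])
    vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1]]))
    if (any(is.na(vals)))
      stop("cannot parse numeric row at line ", i, " of ", path,
           call. = FALSE)
    vals
  }
  build <- function(row_idx, label) {
    rows <- lapply(row_idx, parse_row)
    lens <- lengths(rows)
    if (length(unique(lens)) != 1)
      stop("ragged rows in block ", label, " near line ", row_idx[1],
           " of ", path, call. = FALSE)
    do.call(rbind, rows)
  }
  if (labelled) {
    starts <- grep("^\\s*[ABC]\\s*:\\s*$", lines)
    labels <- trimws(sub(":.*", "", lines[starts]))
    blocks <- list()
    bounds <- c(starts, length(lines) + 1L)
    for (k in seq_along(starts)) {
      idx <- seq(starts[k] + 1L, bounds[k + 1L] - 1L)
      idx <- idx[nzchar(trimws(lines[idx]))]
      if (length(idx) == 0)
        stop("empty block ", labels[k], " at line ", starts[k], " of ",
             path, call. = FALSE)
      blocks[[labels[k]]] <- build(idx, labels[k])
    }
    for (lab in c("A", "B", "C"))
      if (is.null(blocks[[lab]]))
        stop("missing block \"", lab, "\" in ", path, call. = FALSE)
    make_system(blocks$A, blocks$B, blocks$C)
  } else {
    nonblank <- nzchar(trimws(lines))
    if (!any(nonblank)) stop("empty system file: ", path, call. = FALSE)
    runs <- split(which(nonblank), cumsum(!nonblank)[nonblank])
    if (length(runs) != 3)
      stop("unlabelled system file must hold exactly 3 blank-line-",
           "separated blocks (A, B, C); found ", length(runs), " in ",
           path, call. = FALSE)
    make_system(build(runs[[1]], "A"), build(runs[[2]], "B"),
                build(runs[[3]], "C"))
  }
}

#' Reproduce the package's standard tables
#'
#' Deterministic recipes, keyed by the quantity they tabulate:
#' \describe{
#'   \item{`oscillator_phenotype`}{impulse-response phenotype of the
#'     two-gene oscillator, \eqn{\sin t + \cos t}, on the default grid.}
#'   \item{`rewired_dynamics`}{gene-level (kryptotype) impulse dynamics
#'     of the equivalent systems A(0) and A(-2): identical gene-1
#'     output, different hidden gene-2 dynamics.}
#'   \item{`hybrid_phenotypes`}{phenotype trajectories of the F1 and of
#'     all 81 enumerated F2 hybrids between A(0) and each of A(1/100),
#'     A(1/10), A(1/2).}
#'   \item{`breakdown`}{the hybrid-breakdown curve (mean F1/F2 distance
#'     to optimum vs eps and genetic distance).}
#' }
#'
#' @param recipe one of the names above.
#' @param t_max,points time grid (defaults: 400 points on `[0, 4*pi]`).
#' @param eps parameter grid for `hybrid_phenotypes` / `breakdown`.
#' @param seed recorded and applied for any stochastic step (the default
#'   recipes are fully deterministic).
#' @param out_dir if non-`NULL`, the table is also written as a TSV named
#'   after the recipe, together with a `<recipe>.log` recording the
#'   resolved configuration.
#' @return a data frame (invisibly also written to `out_dir`).
#' @export
run_figure <- function(recipe = c("oscillator_phenotype", "rewired_dynamics",
                                  "hybrid_phenotypes", "breakdown"),
                       t_max = 4 * pi, points = 400,
                       eps = NULL, seed = 1, out_dir = NULL) {
  recipe <- match.arg(recipe)
  times <- seq(0, t_max, length.out = points)
  st <- local_rng(seed)
  on.exit(restore_rng(st))
  tab <- switch(recipe,
    oscillator_phenotype = {
      h <- impulse_response(oscillator(), times)
      data.frame(time = times, phenotype = drop(h$values))
    },
    rewired_dynamics = {
      sys_list <- list(`0` = oscillator_family(0), `-2` = oscillator_family(-2))
      do.call(rbind, lapply(names(sys_list), function(tau) {
        s <- sys_list[[tau]]
        kry <- t(vapply(times, function(t)
          as.numeric(expm_mat(s$A * t) %*% s$B), numeric(2)))
        data.frame(tau = as.numeric(tau), time = times,
                   gene1 = kry[, 1], gene2 = kry[, 2])
      }))
    },
    hybrid_phenotypes = {
      if (is.null(eps)) eps <- c(1 / 100, 1 / 10, 1 / 2)
      do.call(rbind, lapply(eps, function(e) {
        p1 <- oscillator_family(0); p2 <- oscillator_family(e)
        map <- locus_map_A(p1)
        g1 <- homozygous_genotype(map, p1)
        g2 <- homozygous_genotype(map, p2)
        f1 <- diploid_system(diploid_genotype(map, g1$hap1, g2$hap1))
        f2 <- f2_enumerate(g1, g2)
        hybrids <- c(list(f1), f2$systems)
        labels <- c("F1", rep("F2", length(f2$systems)))
        do.call(rbind, lapply(seq_along(hybrids), function(k) {
          h <- impulse_response(hybrids[[k]], times)
          data.frame(eps = e, hybrid = labels[k],
                     genotype = k - 1L, time = times,
                     phenotype = drop(h$values))
        }))
      }))
    },
    breakdown = {
      if (is.null(eps))
        eps <- 10^seq(log10(1e-3), log10(0.5), length.out = 12)
      breakdown_curve(eps, seed = seed)
    })
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(tab, file.path(out_dir, paste0(recipe, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(paste("recipe:", recipe),
                 paste("package_version:",
                       as.character(utils::packageVersion("sysdrift"))),
                 paste("seed:", seed),
                 paste("t_max:", t_max), paste("points:", points),
                 paste("eps:", paste(eps, collapse = ",")),
                 paste("generated:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
               file.path(out_dir, paste0(recipe, ".log")))
  }
  tab
}
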