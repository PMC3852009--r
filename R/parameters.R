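#' Haplotype labels of the two-locus, two-allele model
#'
#' The four haplotypes at a pair of interacting biallelic loci, in the
#' fixed order used everywhere in this package (vectors, matrices, files):
#' `AB, aB, Ab, ab`. `AB` is the ancestral high-fitness haplotype, `ab`
#' the derived compensated haplotype (also fitness 1), and `aB`, `Ab` the
#' deleterious single-mutant intermediates (fitness `1 - s`).
#'
#' @return Character vector of the four haplotype labels.
#' @export
#' @examples
#' haplotypes()
haplotypes <- function() c("AB", "aB", "Ab", "ab")

#' Fitness class of each haplotype
#'
#' Haplotypes are partitioned into the fit class `Y = {AB, ab}` (fitness 1)
#' and the deleterious class `X = {aB, Ab}` (fitness `1 - s`).
#'
#' @param h Haplotype label(s), a subset of [haplotypes()].
#' @return Character vector of `"Y"` or `"X"`, one per input haplotype.
#' @export
#' @examples
#' haplotype_class(c("AB", "aB"))
haplotype_class <- function(h) {
  h <- match_haplotype(h)
  ifelse(h %in% c("AB", "ab"), "Y", "X")
}

#' Haplotype fitnesses
#'
#' @param s Selection coefficient against the deleterious intermediates,
#'   `0 <= s < 1`.
#' @return Named numeric vector of fitnesses in haplotype order:
#'   `c(AB = 1, aB = 1 - s, Ab = 1 - s, ab = 1)`.
#' @export
haplotype_fitness <- function(s) {
  stopifnot(is.numeric(s), length(s) == 1, s >= 0, s < 1)
  stats::setNames(c(1, 1 - s, 1 - s, 1), haplotypes())
}

#' Single-mutation neighbours of a haplotype
#'
#' Two haplotypes are single-mutation neighbours when they differ at
#' exactly one of the two loci. The diagonal partners `AB`/`ab` and
#' `aB`/`Ab` differ at both loci and are never neighbours.
#'
#' @param h A single haplotype label.
#' @return Character vector of the two neighbouring haplotypes.
#' @export
#' @examples
#' single_mutation_neighbors("AB") # aB and Ab
single_mutation_neighbors <- function(h) {
  h <- match_haplotype(h)
  stopifnot(length(h) == 1)
  # bit encoding: AB=0, aB=1, Ab=2, ab=3; one mutation is XOR 1 or XOR 2
  i <- match(h, haplotypes()) - 1L
  haplotypes()[c(bitwXor(i, 1L), bitwXor(i, 2L)) + 1L]
}

match_haplotype <- function(h) {
  h <- as.character(h)
  bad <- !(h %in% haplotypes())
  if (any(bad)) {
    stop("unknown haplotype label(s): ", paste(h[bad], collapse = ", "))
  }
  h
}

#' Model parameters from primitive quantities
#'
#' Constructs the parameter set of the symmetric compensatory model for a
#' population of `N` diploid (equivalently `2N` haploid) individuals. The
#' canonical population size inside the package is the haploid copy number
#' `two_N`; formulas written in terms of the diploid `N` use
#' `N = two_N / 2`.
#'
#' @param two_N Haploid copy number `2N` (positive even integer).
#' @param mu Per-locus, per-copy, per-generation mutation rate (`>= 0`).
#' @param s Selection coefficient against deleterious intermediates,
#'   `0 <= s < 1`.
#' @param rho Recombination rate per individual per generation (`>= 0`).
#' @return An object of class `compsub_params` with elements `two_N`, `N`,
#'   `mu`, `s`, `rho` and derived (never independently stored) quantities
#'   `theta = 4 N mu`, `Ns = N s`, `two_N_rho = 2 N rho` and the
#'   renormalised advantage `t = s / (1 - s)` of a fit haplotype invading a
#'   population fixed for a deleterious intermediate.
#' @seealso [make_parameters()] for construction from population-scaled
#'   quantities.
#' @export
#' @examples
#' p <- model_parameters(200, mu = 2.5e-4, s = 0.01)
#' p$theta # 0.1
model_parameters <- function(two_N, mu, s = 0, rho = 0) {
  if (!is.numeric(two_N) || length(two_N) != 1 || two_N < 2 ||
      two_N != round(two_N)) {
    stop("two_N must be a single integer >= 2")
  }
  if (two_N %% 2 != 0) {
    stop("two_N must be even (it is a diploid population of N = two_N/2)")
  }
  if (!is.numeric(mu) || length(mu) != 1 || mu < 0) {
    stop("mu must be a single non-negative number")
  }
  if (!is.numeric(s) || length(s) != 1 || s < 0 || s >= 1) {
    stop("s must satisfy 0 <= s < 1 (got s = ", format(s), ")")
  }
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0) {
    stop("rho must be a single non-negative number")
  }
  two_N <- as.integer(two_N)
  N <- two_N / 2
  structure(
    list(two_N = two_N, N = N, mu = mu, s = s, rho = rho,
         theta = 4 * N * mu, Ns = N * s, two_N_rho = two_N * rho,
         t = s / (1 - s)),
    class = "compsub_params"
  )
}

#' Model parameters from population-scaled quantities
#'
#' The conventional reporting scale for this model: the population-scaled
#' mutation rate `theta = 4 N mu` per locus per generation, the scaled
#' selection intensity `Ns`, and the scaled recombination rate
#' `2 N rho` per generation, with `N` the diploid population size
#' (`two_N / 2` haploid copies).
#'
#' @param two_N Haploid copy number `2N`.
#' @param theta Scaled mutation rate `4 N mu` (`>= 0`).
#' @param Ns Scaled selection coefficient `N s` (`>= 0`, and `Ns / N < 1`).
#' @param two_N_rho Scaled recombination rate `2 N rho` (`>= 0`).
#' @return A `compsub_params` object; round-trips exactly with
#'   [model_parameters()].
#' @export
#' @examples
#' p <- make_parameters(two_N = 200, theta = 0.1, Ns = 1)
#' c(p$mu, p$s) # 2.5e-4, 0.01
make_parameters <- function(two_N, theta, Ns = 0, two_N_rho = 0) {
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0) {
    stop("theta must be a single non-negative number")
  }
  if (!is.numeric(Ns) || length(Ns) != 1 || Ns < 0) {
    stop("Ns must be a single non-negative number")
  }
  if (!is.numeric(two_N_rho) || length(two_N_rho) != 1 || two_N_rho < 0) {
    stop("two_N_rho must be a single non-negative number")
  }
  N <- two_N / 2
  if (Ns / N >= 1) {
    stop("Ns implies s = Ns/N = ", format(Ns / N),
         " >= 1; selection coefficient must be below 1 (offending ",
         "parameter: Ns)")
  }
  model_parameters(two_N, mu = theta / (4 * N), s = Ns / N,
                   rho = two_N_rho / two_N)
}

#' @export
print.compsub_params <- function(x, ...) {
  cat("Compensatory-model parameters\n")
  cat(sprintf("  2N = %d haploid copies (N = %g diploids)\n", x$two_N, x$N))
  cat(sprintf("  mu = %g  (theta = 4N mu = %g)\n", x$mu, x$theta))
  cat(sprintf("  s  = %g  (Ns = %g, t = s/(1-s) = %g)\n", x$s, x$Ns, x$t))
  cat(sprintf("  rho = %g (2N rho = %g)\n", x$rho, x$two_N_rho))
  invisible(x)
}

#' Population state: haplotype counts
#'
#' A population state is the vector of haplotype copy counts, in haplotype
#' order, summing to `2N`, together with a generation index.
#'
#' @param counts Integer vector of length 4 (AB, aB, Ab, ab counts).
#' @param generation Non-negative generation index.
#' @return A named integer vector of class `compsub_state` with a
#'   `generation` attribute.
#' @export
#' @examples
#' population_state(c(199, 1, 0, 0))
population_state <- function(counts, generation = 0) {
  counts <- as.integer(counts)
  if (length(counts) != 4 || any(counts < 0)) {
    stop("counts must be 4 non-negative integers in haplotype order")
  }
  if (generation < 0) stop("generation must be non-negative")
  structure(stats::setNames(counts, haplotypes()),
            generation = as.numeric(generation), class = "compsub_state")
}

#' Fixed haplotype of a population state, if any
#'
#' @param counts Haplotype counts (length-4 vector).
#' @return The label of the haplotype carrying every copy, or `NA_character_`
#'   when the population is polymorphic.
#' @export
fixed_haplotype <- function(counts) {
  counts <- as.integer(counts)
  total <- sum(counts)
  i <- which(counts == total)
  if (length(i) == 1) haplotypes()[i] else NA_character_
}
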