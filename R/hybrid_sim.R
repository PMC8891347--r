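#' The six genotype-frequency classes
#'
#' Each class is defined by its ancestry-pair proportion triple
#' `phi = (phi00, phi01, phi11)`: the probability that a locus's two gene
#' copies derive, respectively, both from population 0, one from each, or
#' both from population 1. In the sockeye/kokanee case study population 0
#' is kokanee and population 1 sockeye; `BC0` is the first backcross to
#' kokanee (F1 x pure0) and `BC1` the first backcross to sockeye.
#'
#' @return data frame with columns `class`, `phi00`, `phi01`, `phi11` in
#'   the canonical class order `pure0, pure1, F1, F2, BC0, BC1`.
#' @export
hybrid_classes <- function() {
  data.frame(
    class = HYBRID_CLASSES,
    phi00 = c(1, 0, 0, 0.25, 0.5, 0),
    phi01 = c(0, 0, 1, 0.50, 0.5, 0.5),
    phi11 = c(0, 1, 0, 0.25, 0, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Ancestry-pair proportions of one class
#'
#' @param name class name, one of `pure0, pure1, F1, F2, BC0, BC1`.
#' @return numeric triple `(phi00, phi01, phi11)`.
#' @export
class_phi <- function(name) {
  tab <- hybrid_classes()
  i <- match(name, tab$class)
  if (is.na(i)) stop_param("unknown hybrid class: ", name)
  unlist(tab[i, c("phi00", "phi01", "phi11")])
}

# Gamete-origin distribution of each class: probability that a transmitted
# gene copy originates from pop0 / pop1. Used to derive phi by pedigree.
gamete_origin <- function(name) {
  switch(name,
         pure0 = c(1, 0),
         pure1 = c(0, 1),
         F1 = c(0.5, 0.5),
         stop_param("no gamete-origin distribution for class: ", name))
}

# Parent classes whose cross produces each of the six classes.
class_pedigree <- function(name) {
  switch(name,
         pure0 = c("pure0", "pure0"),
         pure1 = c("pure1", "pure1"),
         F1 = c("pure0", "pure1"),
         F2 = c("F1", "F1"),
         BC0 = c("F1", "pure0"),
         BC1 = c("F1", "pure1"),
         stop_param("unknown hybrid class: ", name))
}

#' Derive phi from the pedigree
#'
#' Computes the ancestry-pair triple of a class as the outer product of its
#' parents' gamete-origin distributions — the Mendelian route to the stored
#' [class_phi()] values.
#'
#' @inheritParams class_phi
#' @return numeric triple `(phi00, phi01, phi11)`.
#' @export
class_phi_from_pedigree <- function(name) {
  par <- class_pedigree(name)
  ga <- gamete_origin(par[1])
  gb <- gamete_origin(par[2])
  c(phi00 = ga[1] * gb[1],
    phi01 = ga[1] * gb[2] + ga[2] * gb[1],
    phi11 = ga[2] * gb[2])
}

# Draw one gamete (allele + origin) per locus from a pure-population parent
# whose genotype is itself drawn from HWE at freqs p. Returns an n x L
# 0/1 allele matrix. Vectorized over individuals and loci.
pure_gametes <- function(n, p) {
  L <- length(p)
  parent <- matrix(rbinom(n * L, 2L, rep(p, each = n)), nrow = n)
  # transmitted copy is a uniform draw among the parent's two copies
  matrix(rbinom(n * L, 1L, parent / 2), nrow = n)
}

# Gametes from n independent F1 parents: each F1 carries one pop0-origin
# and one pop1-origin copy; per locus the gamete takes either copy with
# probability 1/2 (unlinked loci segregate independently).
f1_gametes <- function(n, p0, p1) {
  copy0 <- pure_gametes(n, p0)   # the F1's pop0-derived copy
  copy1 <- pure_gametes(n, p1)   # the F1's pop1-derived copy
  pick1 <- matrix(rbinom(n * length(p0), 1L, 0.5), nrow = n)
  copy0 * (1L - pick1) + copy1 * pick1
}

class_gametes <- function(class, n, p0, p1) {
  switch(class,
         pure0 = pure_gametes(n, p0),
         pure1 = pure_gametes(n, p1),
         F1 = f1_gametes(n, p0, p1),
         stop_param("unknown parent class: ", class))
}

#' Simulate individuals of one genotype-frequency class
#'
#' Explicit Mendelian crossing: for every simulated individual, fresh
#' parents are drawn from Hardy-Weinberg equilibrium at the reference
#' allele frequencies, crossed according to the class pedigree (F1 =
#' pure0 x pure1, F2 = F1 x F1, BC0 = F1 x pure0, BC1 = F1 x pure1), and
#' gametes segregate independently per locus (panel loci are assumed
#' unlinked, as after linkage pruning).
#'
#' @param class class name, one of `pure0, pure1, F1, F2, BC0, BC1`.
#' @param n number of individuals.
#' @param freqs0,freqs1 per-locus alternate-allele frequencies of the two
#'   parental populations (equal length).
#' @param seed integer seed.
#' @return integer matrix, `n` x loci, of alt-allele counts 0/1/2.
#' @export
simulate_class_individuals <- function(class, n, freqs0, freqs1, seed = 1L) {
  if (length(freqs0) != length(freqs1)) {
    stop_param("freqs0 and freqs1 must have equal length")
  }
  if (n < 1) stop_param("n must be >= 1")
  if (!class %in% HYBRID_CLASSES) stop_param("unknown hybrid class: ", class)
  set.seed(seed)
  par <- class_pedigree(class)
  g <- class_gametes(par[1], n, freqs0, freqs1) +
    class_gametes(par[2], n, freqs0, freqs1)
  storage.mode(g) <- "integer"
  g
}
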