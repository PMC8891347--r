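#' Parameters for the synthetic RAD-like reference dataset
#'
#' Bundles the parameters of the Balding-Nichols two-population model used
#' by [simulate_rad_dataset()]. The generator emulates a RAD-seq screen of
#' two diverged populations of the same species (e.g. resident kokanee and
#' anadromous sockeye salmon): thousands of biallelic SNPs whose
#' per-population allele frequencies are drawn around a shared ancestral
#' frequency, an outlier tail of highly differentiated loci arising from the
#' Beta divergence model, missing genotypes, a small number of
#' near-duplicate (linked) locus pairs, and homeolog-like loci with fixed
#' heterozygosity as produced by collapsed salmonid paralogs.
#'
#' @param n_loci total number of loci, including linked duplicates and
#'   homeolog-like loci.
#' @param ancestral_freq_range range from which ancestral allele frequencies
#'   are drawn uniformly; kept away from 0/1 so loci are rarely monomorphic.
#' @param divergence_F Balding-Nichols differentiation parameter in (0,1);
#'   the expected FST between each population and the ancestral pool.
#' @param n_pop0,n_pop1 diploid sample sizes of the two reference
#'   populations (defaults mirror a 20-fish kokanee and 35-fish sockeye
#'   reference collection).
#' @param missing_rate fraction of genotype calls set missing, uniformly at
#'   random over the matrix.
#' @param n_linked_pairs number of loci duplicated as near-identical copies
#'   (>= 95% genotype identity) to exercise linkage pruning.
#' @param n_homeolog_like number of loci forced to all-heterozygote in both
#'   populations, mimicking collapsed homeologs.
#' @param tag_length RAD tag length in base pairs; each locus gets a SNP
#'   position drawn uniformly on `[1, tag_length]`.
#' @param seed integer seed making the dataset reproducible.
#' @return an object of class `population_model` (a validated list).
#' @export
population_model <- function(n_loci = 3000,
                             ancestral_freq_range = c(0.1, 0.9),
                             divergence_F = 0.15,
                             n_pop0 = 20,
                             n_pop1 = 35,
                             missing_rate = 0.05,
                             n_linked_pairs = 25,
                             n_homeolog_like = 50,
                             tag_length = 90,
                             seed = 1L) {
  m <- list(
    n_loci = as.integer(n_loci),
    ancestral_freq_range = as.numeric(ancestral_freq_range),
    divergence_F = divergence_F,
    n_pop0 = as.integer(n_pop0),
    n_pop1 = as.integer(n_pop1),
    missing_rate = missing_rate,
    n_linked_pairs = as.integer(n_linked_pairs),
    n_homeolog_like = as.integer(n_homeolog_like),
    tag_length = as.integer(tag_length),
    seed = as.integer(seed)
  )
  if (!(m$divergence_F > 0 && m$divergence_F < 1)) {
    stop_param("divergence_F must be in (0, 1)")
  }
  if (!(m$missing_rate >= 0 && m$missing_rate < 1)) {
    stop_param("missing_rate must be in [0, 1)")
  }
  if (m$n_pop0 < 2 || m$n_pop1 < 2) {
    stop_param("sample sizes must be >= 2")
  }
  if (m$n_loci < 1) stop_param("n_loci must be positive")
  if (length(m$ancestral_freq_range) != 2 ||
      m$ancestral_freq_range[1] <= 0 || m$ancestral_freq_range[2] >= 1 ||
      m$ancestral_freq_range[1] > m$ancestral_freq_range[2]) {
    stop_param("ancestral_freq_range must be an increasing pair inside (0, 1)")
  }
  if (m$n_homeolog_like + 2L * m$n_linked_pairs > m$n_loci) {
    stop_param("n_homeolog_like + 2 * n_linked_pairs cannot exceed n_loci")
  }
  if (m$tag_length < 1) stop_param("tag_length must be >= 1")
  class(m) <- "population_model"
  m
}

#' Simulate a RAD-like two-population reference panel
#'
#' Draws, per locus, an ancestral allele frequency uniformly from
#' `ancestral_freq_range` and the two population frequencies from the
#' Balding-Nichols Beta distribution
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, then samples diploid
#' genotypes binomially for each individual. Loci that come out monomorphic
#' in both samples are redrawn. `n_linked_pairs` loci are then duplicated
#' with at least 95% genotype identity, `n_homeolog_like` loci are forced
#' to all-heterozygote in both populations, and `missing_rate` of calls are
#' masked. Deterministic given `model$seed`.
#'
#' @param model a [population_model()].
#' @return an object of class `ref_panel`: a list with
#'   \describe{
#'     \item{geno}{integer matrix, individuals x loci, alt-allele counts
#'       0/1/2 with `NA` for missing.}
#'     \item{pop}{factor of length `nrow(geno)` with levels `pop0`, `pop1`.}
#'     \item{loci}{data frame of locus records: `locus_id`, `tag_length`,
#'       `snp_pos`, `type` (`snp`, `linked_dup`, `homeolog`), `source`
#'       (source locus of a duplicate, else `NA`).}
#'     \item{truth}{data frame of the generating frequencies `p0`, `p1`
#'       (NA for homeolog-like loci, which have no frequency model).}
#'   }
#' @export
simulate_rad_dataset <- function(model) {
  stopifnot(inherits(model, "population_model"))
  set.seed(model$seed)
  n_loci <- model$n_loci
  n0 <- model$n_pop0
  n1 <- model$n_pop1
  FF <- model$divergence_F
  n_dup <- model$n_linked_pairs
  n_hom <- model$n_homeolog_like
  # base loci drawn from the frequency model; duplicates and homeologs are
  # carved out of the total so n_loci is exactly what comes back
  n_base <- n_loci - n_dup - n_hom

  draw_loci <- function(k) {
    p_anc <- runif(k, model$ancestral_freq_range[1], model$ancestral_freq_range[2])
    a <- p_anc * (1 - FF) / FF
    b <- (1 - p_anc) * (1 - FF) / FF
    p0 <- rbeta(k, a, b)
    p1 <- rbeta(k, a, b)
    g0 <- matrix(rbinom(n0 * k, 2L, rep(p0, each = n0)), nrow = n0)
    g1 <- matrix(rbinom(n1 * k, 2L, rep(p1, each = n1)), nrow = n1)
    list(p0 = p0, p1 = p1, g0 = g0, g1 = g1)
  }

  d <- draw_loci(n_base)
  # redraw loci monomorphic across both samples (no information content)
  repeat {
    mono <- colSums(d$g0) + colSums(d$g1)
    bad <- which(mono == 0L | mono == 2L * (n0 + n1))
    if (!length(bad)) break
    r <- draw_loci(length(bad))
    d$p0[bad] <- r$p0; d$p1[bad] <- r$p1
    d$g0[, bad] <- r$g0; d$g1[, bad] <- r$g1
  }

  geno <- rbind(d$g0, d$g1)
  p0 <- d$p0; p1 <- d$p1
  type <- rep("snp", n_base)
  source_id <- rep(NA_character_, n_base)
  ids <- sprintf("L%05d", seq_len(n_base))

  # near-duplicate loci: copy a source locus, resampling a capped handful of
  # genotypes so identity stays >= 95%
  if (n_dup > 0) {
    src <- sample.int(n_base, n_dup)
    n_ind <- n0 + n1
    max_flips <- floor(0.05 * n_ind)
    for (j in seq_len(n_dup)) {
      gcol <- geno[, src[j]]
      k <- min(rbinom(1L, n_ind, 0.03), max_flips)
      if (k > 0) {
        at <- sample.int(n_ind, k)
        gcol[at] <- sample(0:2, k, replace = TRUE)
      }
      geno <- cbind(geno, gcol)
      p0 <- c(p0, d$p0[src[j]]); p1 <- c(p1, d$p1[src[j]])
      type <- c(type, "linked_dup")
      source_id <- c(source_id, ids[src[j]])
      ids <- c(ids, sprintf("L%05d", n_base + j))
    }
  }

  if (n_hom > 0) {
    hom <- matrix(1L, nrow = n0 + n1, ncol = n_hom)
    geno <- cbind(geno, hom)
    p0 <- c(p0, rep(NA_real_, n_hom)); p1 <- c(p1, rep(NA_real_, n_hom))
    type <- c(type, rep("homeolog", n_hom))
    source_id <- c(source_id, rep(NA_character_, n_hom))
    ids <- c(ids, sprintf("L%05d", n_base + n_dup + seq_len(n_hom)))
  }

  storage.mode(geno) <- "integer"
  colnames(geno) <- ids
  rownames(geno) <- c(sprintf("pop0_%03d", seq_len(n0)),
                      sprintf("pop1_%03d", seq_len(n1)))

  if (model$missing_rate > 0) {
    miss <- runif(length(geno)) < model$missing_rate
    geno[miss] <- NA_integer_
  }

  snp_pos <- sample.int(model$tag_length, n_loci, replace = TRUE)

  panel <- list(
    geno = geno,
    pop = factor(rep(c("pop0", "pop1"), c(n0, n1)), levels = c("pop0", "pop1")),
    loci = data.frame(
      locus_id = ids,
      tag_length = model$tag_length,
      snp_pos = snp_pos,
      type = type,
      source = source_id,
      stringsAsFactors = FALSE
    ),
    truth = data.frame(locus_id = ids, p0 = p0, p1 = p1,
                       stringsAsFactors = FALSE)
  )
  class(panel) <- "ref_panel"
  panel
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("ref_panel:", nrow(x$geno), "individuals x", ncol(x$geno), "loci\n")
  cat("  pop0:", sum(x$pop == "pop0"), " pop1:", sum(x$pop == "pop1"), "\n")
  cat("  missing:", sprintf("%.1f%%", 100 * mean(is.na(x$geno))), "\n")
  invisible(x)
}

#' Restrict a reference panel to a set of loci
#'
#' @param panel a `ref_panel`.
#' @param locus_ids character vector of locus ids (order preserved).
#' @return a `ref_panel` with only those loci.
#' @export
subset_ref_panel <- function(panel, locus_ids) {
  stopifnot(inherits(panel, "ref_panel"))
  missing_ids <- setdiff(locus_ids, colnames(panel$geno))
  if (length(missing_ids)) {
    stop_param("unknown locus ids: ", paste(head(missing_ids, 5), collapse = ", "))
  }
  structure(list(
    geno = panel$geno[, locus_ids, drop = FALSE],
    pop = panel$pop,
    loci = panel$loci[match(locus_ids, panel$loci$locus_id), , drop = FALSE],
    truth = if (!is.null(panel$truth)) {
      panel$truth[match(locus_ids, panel$truth$locus_id), , drop = FALSE]
    }
  ), class = "ref_panel")
}

#' Split a reference panel's genotypes by population
#'
#' @param panel a `ref_panel`.
#' @return list with integer matrices `g0` and `g1`.
#' @export
split_populations <- function(panel) {
  stopifnot(inherits(panel, "ref_panel"))
  list(g0 = panel$geno[panel$pop == "pop0", , drop = FALSE],
       g1 = panel$geno[panel$pop == "pop1", , drop = FALSE])
}

#' Simulate a mixed cohort of known hybrid classes
#'
#' Generates individuals of the requested genotype-frequency classes by
#' explicit Mendelian crossing (see [simulate_class_individuals()]) from
#' per-locus parental allele frequencies, optionally masks genotypes at
#' `missing_rate`, and returns the truth labels alongside the matrix —
#' the cohort analogue of a field sample of spawners with known ancestry.
#'
#' @param freqs0,freqs1 per-locus alternate-allele frequencies of the two
#'   parental populations (equal length).
#' @param class_counts named integer vector; names must be a subset of
#'   `pure0, pure1, F1, F2, BC0, BC1`.
#' @param missing_rate fraction of calls masked uniformly at random.
#' @param seed integer seed.
#' @return list with `geno` (individuals x loci integer matrix) and
#'   `labels` (character vector of true classes).
#' @export
simulate_cohort <- function(freqs0, freqs1, class_counts,
                            missing_rate = 0, seed = 1L) {
  if (length(freqs0) != length(freqs1)) {
    stop_param("freqs0 and freqs1 must have equal length")
  }
  cls <- names(class_counts)
  if (is.null(cls) || !all(cls %in% HYBRID_CLASSES)) {
    stop_param("class_counts names must be among: ",
               paste(HYBRID_CLASSES, collapse = ", "))
  }
  set.seed(seed)
  mats <- list()
  labels <- character(0)
  for (cl in cls) {
    n <- as.integer(class_counts[[cl]])
    if (n <= 0) next
    # per-class seed drawn from the seeded stream keeps the whole cohort
    # reproducible while letting classes be generated independently
    g <- simulate_class_individuals(cl, n, freqs0, freqs1,
                                    seed = sample.int(.Machine$integer.max, 1L))
    rownames(g) <- sprintf("%s_%04d", cl, seq_len(n))
    mats[[length(mats) + 1L]] <- g
    labels <- c(labels, rep(cl, n))
  }
  geno <- do.call(rbind, mats)
  if (missing_rate > 0) {
    miss <- runif(length(geno)) < missing_rate
    geno[miss] <- NA_integer_
  }
  list(geno = geno, labels = labels)
}
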