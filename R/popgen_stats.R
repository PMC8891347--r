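#' Per-locus summary statistics for two reference populations
#'
#' Computes, from two genotype vectors at a single biallelic locus, the
#' quantities the panel filter chain ranks and screens on: per-population
#' call rate, pooled minor allele frequency, observed heterozygosity, Fis,
#' Hardy-Weinberg exact p-values, and the two-population Weir-Cockerham
#' theta. Missing genotypes are excluded from every denominator (pairwise
#' deletion). Fis is `1 - Hobs/Hexp` with `Hexp = 2 p (1 - p)` from the
#' same sample, and is `NA` with `fis_defined_* = FALSE` when the sample
#' is monomorphic (`Hexp = 0`).
#'
#' @param genotypes_pop0,genotypes_pop1 vectors of alt-allele counts
#'   (0/1/2, `NA` = missing), one element per diploid individual.
#' @return one-row data frame with columns `call_rate_pop0`,
#'   `call_rate_pop1`, `maf_pooled`, `hobs_pop0`, `hobs_pop1`, `fis_pop0`,
#'   `fis_pop1`, `fis_defined_pop0`, `fis_defined_pop1`, `hwe_p_pop0`,
#'   `hwe_p_pop1`, `theta`, `theta_defined`.
#' @export
locus_summary <- function(genotypes_pop0, genotypes_pop1) {
  if (!length(genotypes_pop0) || !length(genotypes_pop1)) {
    stop_param("genotype vectors must be nonempty")
  }
  check_genotype_codes(genotypes_pop0)
  check_genotype_codes(genotypes_pop1)

  one_pop <- function(g) {
    called <- g[!is.na(g)]
    n <- length(called)
    if (n == 0) {
      return(list(call_rate = 0, p = NA_real_, hobs = NA_real_,
                  fis = NA_real_, fis_defined = FALSE, hwe_p = NA_real_))
    }
    p <- sum(called) / (2 * n)
    hobs <- mean(called == 1L)
    hexp <- 2 * p * (1 - p)
    fis_defined <- hexp > 0
    fis <- if (fis_defined) 1 - hobs / hexp else NA_real_
    hwe_p <- hwe_exact_test(sum(called == 0L), sum(called == 1L),
                            sum(called == 2L))
    list(call_rate = n / length(g), p = p, hobs = hobs,
         fis = fis, fis_defined = fis_defined, hwe_p = hwe_p)
  }

  s0 <- one_pop(genotypes_pop0)
  s1 <- one_pop(genotypes_pop1)

  pooled <- c(genotypes_pop0, genotypes_pop1)
  pooled <- pooled[!is.na(pooled)]
  maf <- if (length(pooled)) {
    p <- sum(pooled) / (2 * length(pooled))
    min(p, 1 - p)
  } else NA_real_

  th <- tryCatch(weir_cockerham_theta(genotypes_pop0, genotypes_pop1),
                 error = function(e) NA_real_)

  data.frame(
    call_rate_pop0 = s0$call_rate, call_rate_pop1 = s1$call_rate,
    maf_pooled = maf,
    hobs_pop0 = s0$hobs, hobs_pop1 = s1$hobs,
    fis_pop0 = s0$fis, fis_pop1 = s1$fis,
    fis_defined_pop0 = s0$fis_defined, fis_defined_pop1 = s1$fis_defined,
    hwe_p_pop0 = s0$hwe_p, hwe_p_pop1 = s1$hwe_p,
    theta = th, theta_defined = !is.na(th)
  )
}

#' Two-population Weir-Cockerham theta
#'
#' Variance-components estimator of FST for one biallelic locus and two
#' populations: theta = a / (a + b + c), where a, b, c are the
#' among-population, among-individual-within-population, and
#' within-individual components computed from sample sizes, allele
#' frequencies and observed heterozygote fractions. Returns `NA` when the
#' total variance `a + b + c` is zero (locus monomorphic in both samples);
#' small negative estimates are expected behaviour of the estimator.
#'
#' @inheritParams locus_summary
#' @return a single numeric theta in `[-1, 1]`, or `NA` when undefined.
#' @export
weir_cockerham_theta <- function(genotypes_pop0, genotypes_pop1) {
  g0 <- genotypes_pop0[!is.na(genotypes_pop0)]
  g1 <- genotypes_pop1[!is.na(genotypes_pop1)]
  if (length(g0) < 2 || length(g1) < 2) {
    stop_param("need >= 2 called genotypes in each population")
  }
  check_genotype_codes(g0)
  check_genotype_codes(g1)
  r <- 2
  n_i <- c(length(g0), length(g1))
  p_i <- c(sum(g0), sum(g1)) / (2 * n_i)
  h_i <- c(mean(g0 == 1L), mean(g1 == 1L))

  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)

  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2

  denom <- a + b + cc
  if (abs(denom) < .Machine$double.eps * 8) return(NA_real_)
  a / denom
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on one biallelic locus: given the observed allele
#' counts, enumerates the probability of every heterozygote count of the
#' correct parity under the HWE sampling distribution and sums the
#' probabilities of configurations no more likely than the observed one
#' (two-sided). Monomorphic samples return p = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) {
    stop_param("genotype counts must be nonnegative")
  }
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop_param("at least one genotype required")
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0 || n_rare == 2 * n) return(1)

  # probabilities over all heterozygote counts with the parity of n_rare,
  # built by the standard two-directional recurrence from the mode
  het_vals <- seq.int(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  probs <- setNames(numeric(length(het_vals)), het_vals)

  # start at (or near) the distribution mode for numerical stability
  mid <- floor(n_rare * (2 * n - n_rare) / (2 * n))
  if (mid %% 2 != n_rare %% 2) mid <- mid + 1
  idx0 <- match(mid, het_vals)
  probs[idx0] <- 1

  # downward recurrence: P(het - 2) = P(het) * het (het - 1) /
  #                      ((rare_hom + 1)(common_hom + 1) * 4)
  het <- mid
  while (het >= 2) {
    rare_hom <- (n_rare - het) / 2
    common_hom <- n - het - rare_hom
    i <- match(het, het_vals)
    probs[i - 1] <- probs[i] * het * (het - 1) /
      (4 * (rare_hom + 1) * (common_hom + 1))
    het <- het - 2
  }
  # upward recurrence
  het <- mid
  while (het + 2 <= max(het_vals)) {
    rare_hom <- (n_rare - het) / 2
    common_hom <- n - het - rare_hom
    i <- match(het, het_vals)
    probs[i + 1] <- probs[i] * 4 * rare_hom * common_hom /
      ((het + 2) * (het + 1))
    het <- het + 2
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, het_vals)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Genotypic linkage-disequilibrium permutation test
#'
#' Tests association between the genotype vectors of two loci with a
#' log-likelihood-ratio (G) statistic on their 3x3 genotype contingency
#' table, against a permutation null obtained by shuffling one locus's
#' genotypes across individuals. Individuals missing at either locus are
#' dropped pairwise. The p-value is `(1 + #{G_perm >= G_obs}) /
#' (1 + n_permutations)`, so it is always in (0, 1]. If either locus has
#' fewer than two distinct genotype categories after deletion, no test is
#' possible: p = 1 with `degenerate = TRUE`.
#'
#' @param genotypes_a,genotypes_b equal-length genotype vectors (0/1/2/NA).
#' @param n_permutations number of label shuffles.
#' @param seed integer seed for the permutation stream.
#' @return list with `p`, the observed `G`, `n_used`, and `degenerate`.
#' @export
ld_genotypic_test <- function(genotypes_a, genotypes_b,
                              n_permutations = 999, seed = 1L) {
  if (length(genotypes_a) != length(genotypes_b)) {
    stop_param("genotype vectors must have equal length")
  }
  check_genotype_codes(genotypes_a)
  check_genotype_codes(genotypes_b)
  keep <- !is.na(genotypes_a) & !is.na(genotypes_b)
  ga <- as.integer(genotypes_a[keep])
  gb <- as.integer(genotypes_b[keep])
  if (length(unique(ga)) < 2 || length(unique(gb)) < 2 || length(ga) < 2) {
    return(list(p = 1, G = 0, n_used = length(ga), degenerate = TRUE))
  }
  res <- perm_g_test(ga, gb, as.integer(n_permutations), as.integer(seed))
  list(p = res$p, G = res$G, n_used = length(ga), degenerate = FALSE)
}

#' Locus statistics table for a reference panel
#'
#' Applies [locus_summary()] to every locus of a `ref_panel` and binds the
#' results to the locus metadata, giving the table the filter chain
#' operates on.
#'
#' @param panel a `ref_panel` from [simulate_rad_dataset()] or
#'   [read_genotypes()] with a population factor.
#' @return data frame: locus metadata columns followed by the
#'   [locus_summary()] columns, one row per locus.
#' @export
locus_stats_table <- function(panel) {
  stopifnot(inherits(panel, "ref_panel"))
  sp <- split_populations(panel)
  rows <- lapply(seq_len(ncol(panel$geno)), function(j) {
    locus_summary(sp$g0[, j], sp$g1[, j])
  })
  cbind(panel$loci, do.call(rbind, rows))
}
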