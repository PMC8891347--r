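# Shared fixture builders. Everything is generated in code at test time.

CLASSES <- c("pure0", "pure1", "F1", "F2", "BC0", "BC1")

# minimal ref_panel from two genotype matrices
make_ref_panel <- function(g0, g1, snp_pos = NULL, tag_length = 90L) {
  geno <- rbind(g0, g1)
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("L%03d", seq_len(ncol(geno)))
  }
  rownames(geno) <- sprintf("i%03d", seq_len(nrow(geno)))
  storage.mode(geno) <- "integer"
  loci <- data.frame(
    locus_id = colnames(geno), tag_length = tag_length,
    snp_pos = snp_pos %||% rep(50L, ncol(geno)),
    stringsAsFactors = FALSE)
  structure(list(
    geno = geno,
    pop = factor(rep(c("pop0", "pop1"), c(nrow(g0), nrow(g1))),
                 levels = c("pop0", "pop1")),
    loci = loci, truth = NULL), class = "ref_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a stats row for filter tests; only the fields the filters look at
stats_row <- function(locus_id, call0 = 1, call1 = 1, maf = 0.3,
                      hobs0 = 0.3, hobs1 = 0.3, fis0 = 0.1, fis1 = 0.1,
                      fis_def0 = TRUE, fis_def1 = TRUE,
                      hwe0 = 0.5, hwe1 = 0.5, theta = 0.2, snp_pos = 50L) {
  data.frame(locus_id = locus_id, tag_length = 90L, snp_pos = snp_pos,
             call_rate_pop0 = call0, call_rate_pop1 = call1,
             maf_pooled = maf, hobs_pop0 = hobs0, hobs_pop1 = hobs1,
             fis_pop0 = fis0, fis_pop1 = fis1,
             fis_defined_pop0 = fis_def0, fis_defined_pop1 = fis_def1,
             hwe_p_pop0 = hwe0, hwe_p_pop1 = hwe1,
             theta = theta, theta_defined = !is.na(theta),
             stringsAsFactors = FALSE)
}

# independent enumeration oracle for the HWE exact test: multinomial
# probabilities of all genotype configurations with the observed allele
# counts, conditional p = sum of probs <= prob(observed)
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  hets <- seq.int(n_alt %% 2, min(n_alt, 2 * n - n_alt), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (n_alt - h) / 2
    rr <- n - h - aa
    lfactorial(n) - lfactorial(rr) - lfactorial(h) - lfactorial(aa) +
      h * log(2) + lfactorial(n_alt) + lfactorial(2 * n - n_alt) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

# independent transcription of the two-population variance-components
# estimator, parameterized by genotype counts (n00, n01, n02) per pop
wc_theta_oracle <- function(counts0, counts1) {
  n_i <- c(sum(counts0), sum(counts1))
  p_i <- c((2 * counts0[1] + counts0[2]) / (2 * n_i[1]),
           (2 * counts1[1] + counts1[2]) / (2 * n_i[2]))
  # p_i above is the REF-allele frequency; the estimator is allele-symmetric
  h_i <- c(counts0[2] / n_i[1], counts1[2] / n_i[2])
  r <- 2
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

counts_to_vec <- function(counts) rep(0:2, counts)

# brute-force genotype probabilities for a class: enumerate ordered
# gene-copy origins and alleles
genotype_prob_oracle <- function(phi, p0, p1) {
  origins <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  wts <- c(phi[1], phi[2] / 2, phi[2] / 2, phi[3])
  pr <- c(g0 = 0, g1 = 0, g2 = 0)
  pv <- c(p0, p1)
  for (k in seq_along(origins)) {
    o <- origins[[k]]
    for (a1 in 0:1) for (a2 in 0:1) {
      w <- wts[k] *
        (if (a1 == 1) pv[o[1] + 1] else 1 - pv[o[1] + 1]) *
        (if (a2 == 1) pv[o[2] + 1] else 1 - pv[o[2] + 1])
      pr[a1 + a2 + 1] <- pr[a1 + a2 + 1] + w
    }
  }
  pr
}

# cache for the expensive full-chain fixture, shared across test files
.chain_cache <- new.env(parent = emptyenv())

# full design chain + 342-locus panel + smoothed frequencies at the
# reference study conditions (3000 loci, F = 0.15, n = 20/35)
synthetic_panel_fixture <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.chain_cache[[key]])) return(.chain_cache[[key]])
  model <- population_model(n_loci = 3000, seed = seed)
  ref <- simulate_rad_dataset(model)
  des <- suppressWarnings(design_panel(ref, seed = seed))
  panel <- des$candidates[seq_len(min(342L, nrow(des$candidates))), ,
                          drop = FALSE]
  panel_ref <- subset_ref_panel(ref, panel$locus_id)
  out <- list(ref = ref, design = des, panel = panel, panel_ref = panel_ref,
              freqs = estimate_reference_frequencies(panel_ref))
  .chain_cache[[key]] <- out
  out
}
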