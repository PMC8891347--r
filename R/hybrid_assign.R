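#' Smoothed reference allele frequencies
#'
#' Estimates per-locus alternate-allele frequencies of the two reference
#' populations with a pseudocount (default 0.5, Jeffreys-style):
#' `(alt_count + pseudocount) / (2 n_called + 2 pseudocount)`. Smoothing
#' keeps every frequency strictly inside (0, 1) so no genotype ever has
#' exactly zero likelihood at loci fixed in a reference sample. A locus
#' with no called genotypes in a population gets frequency 0.5 and an
#' uninformative flag.
#'
#' @param ref_panel a `ref_panel` (genotypes plus population factor).
#' @param pseudocount nonnegative smoothing pseudocount per allele class.
#' @return object of class `ref_freqs`: list with numeric vectors `p0`,
#'   `p1`, integer vectors `n_called0`, `n_called1`, logical
#'   `uninformative` (per locus, either population empty), `locus_id`, and
#'   the `pseudocount`.
#' @export
estimate_reference_frequencies <- function(ref_panel, pseudocount = 0.5) {
  stopifnot(inherits(ref_panel, "ref_panel"))
  if (pseudocount < 0) stop_param("pseudocount must be nonnegative")
  sp <- split_populations(ref_panel)
  one <- function(g) {
    n_called <- colSums(!is.na(g))
    alt <- colSums(g, na.rm = TRUE)
    p <- (alt + pseudocount) / (2 * n_called + 2 * pseudocount)
    p[n_called == 0] <- 0.5
    list(p = p, n_called = n_called)
  }
  e0 <- one(sp$g0)
  e1 <- one(sp$g1)
  structure(list(p0 = e0$p, p1 = e1$p,
                 n_called0 = e0$n_called, n_called1 = e1$n_called,
                 uninformative = e0$n_called == 0 | e1$n_called == 0,
                 locus_id = colnames(ref_panel$geno),
                 pseudocount = pseudocount),
            class = "ref_freqs")
}

#' Genotype probabilities under a genotype-frequency class
#'
#' Under class `phi = (phi00, phi01, phi11)`, a locus's two gene copies
#' derive from (pop0,pop0), (pop0,pop1) or (pop1,pop1) with probabilities
#' phi, and each copy is the alternate allele with its source population's
#' frequency. Mixing over origins gives, with `q = 1 - p`:
#' \deqn{P(g=2) = \phi_{00} p_0^2 + \phi_{01} p_0 p_1 + \phi_{11} p_1^2}
#' \deqn{P(g=1) = \phi_{00} 2 p_0 q_0 + \phi_{01}(p_0 q_1 + q_0 p_1) +
#'   \phi_{11} 2 p_1 q_1}
#' and analogously for `P(g=0)` with the `q`s. Vectorized over loci.
#'
#' @param phi numeric triple from [class_phi()].
#' @param p0,p1 per-locus alternate-allele frequencies in (0, 1).
#' @return matrix with `length(p0)` rows and columns `g0`, `g1`, `g2`;
#'   rows sum to 1.
#' @export
class_genotype_prob <- function(phi, p0, p1) {
  stopifnot(length(phi) == 3, length(p0) == length(p1))
  if (any(p0 <= 0 | p0 >= 1 | p1 <= 0 | p1 >= 1)) {
    stop_param("p0 and p1 must be strictly inside (0, 1); smooth first")
  }
  q0 <- 1 - p0
  q1 <- 1 - p1
  g2 <- phi[1] * p0^2 + phi[2] * p0 * p1 + phi[3] * p1^2
  g1 <- phi[1] * 2 * p0 * q0 + phi[2] * (p0 * q1 + q0 * p1) +
    phi[3] * 2 * p1 * q1
  g0 <- phi[1] * q0^2 + phi[2] * q0 * q1 + phi[3] * q1^2
  cbind(g0 = g0, g1 = g1, g2 = g2)
}

# log P(g | class, locus) for all classes: list over genotype value of
# loci x classes matrices. Shared by the plug-in and Gibbs samplers.
class_loglik_tables <- function(p0, p1) {
  classes <- hybrid_classes()
  L <- length(p0)
  lp <- lapply(1:3, function(i) matrix(NA_real_, L, nrow(classes)))
  for (k in seq_len(nrow(classes))) {
    pr <- class_genotype_prob(unlist(classes[k, c("phi00", "phi01", "phi11")]),
                              p0, p1)
    for (i in 1:3) lp[[i]][, k] <- log(pr[, i])
  }
  names(lp) <- c("g0", "g1", "g2")
  lp
}

# individuals x classes log-likelihood matrix; missing loci contribute 0.
cohort_loglik <- function(geno, lp) {
  ind <- lapply(0:2, function(v) {
    m <- (!is.na(geno)) & geno == v
    storage.mode(m) <- "double"
    m
  })
  ind[[1]] %*% lp$g0 + ind[[2]] %*% lp$g1 + ind[[3]] %*% lp$g2
}

normalize_posterior <- function(loglik, log_prior) {
  lp <- sweep(loglik, 2, log_prior, `+`)
  mx <- apply(lp, 1, max)
  w <- exp(lp - mx)
  w / rowSums(w)
}

assignment_frame <- function(post, loci_used, ids) {
  k <- max.col(post, ties.method = "first")
  mx <- post[cbind(seq_len(nrow(post)), k)]
  tie <- rowSums(abs(post - mx) < 1e-12) > 1
  out <- data.frame(individual = ids, post,
                    max_class = HYBRID_CLASSES[k],
                    max_posterior = mx,
                    loci_used = loci_used,
                    tie = tie,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:7] <- paste0("post_", HYBRID_CLASSES)
  out
}

#' Deterministic plug-in class assignment
#'
#' Assigns each individual to one of the six genotype-frequency classes by
#' plugging the smoothed reference allele frequencies into the class
#' genotype-probability model: per-class log-likelihood summed over
#' non-missing loci, combined with a class prior (uniform by default) and
#' normalized in log space. This is the deterministic counterpart of the
#' MCMC assignment: with informative panels the two agree on virtually
#' every individual, and the plug-in mode is exactly reproducible.
#'
#' @param geno individuals x loci genotype matrix aligned to the
#'   frequency vectors (same loci, same order).
#' @param ref_freqs a `ref_freqs` object, or a list with elements `p0`,
#'   `p1` strictly inside (0, 1).
#' @param prior class prior, length 6 in the canonical order; need not be
#'   normalized.
#' @return data frame (one row per individual): six posterior columns
#'   `post_*` summing to 1, `max_class`, `max_posterior`, `loci_used`, and
#'   `tie` (ties broken by the canonical class order). Individuals with
#'   zero called loci get the (normalized) prior as posterior and a tie
#'   flag when it is flat.
#' @export
assign_plugin <- function(geno, ref_freqs, prior = rep(1, 6)) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  if (ncol(geno) != length(ref_freqs$p0)) {
    stop_param("genotype matrix and reference frequencies disagree on loci")
  }
  check_genotype_codes(geno)
  if (length(prior) != 6 || any(prior < 0) || sum(prior) <= 0) {
    stop_param("prior must be 6 nonnegative weights")
  }
  lp <- class_loglik_tables(ref_freqs$p0, ref_freqs$p1)
  ll <- cohort_loglik(geno, lp)
  post <- normalize_posterior(ll, log(prior / sum(prior)))
  ids <- rownames(geno) %||% sprintf("ind_%04d", seq_len(nrow(geno)))
  assignment_frame(post, rowSums(!is.na(geno)), ids)
}

#' Gibbs-sampling class assignment
#'
#' MCMC counterpart of [assign_plugin()], mirroring the known-reference
#' ("z"/"s" flag) semantics of genotype-frequency-class assignment: the
#' reference individuals inform the allele frequencies but are not members
#' of the test mixture. Each sweep draws (1) per-population allele
#' frequencies from their Beta posteriors given the reference genotypes
#' (Jeffreys Beta(0.5, 0.5) prior), (2) latent class labels for every test
#' individual from the class likelihoods times the mixture proportions,
#' and (3) mixture proportions from a Dirichlet(1,...,1) prior updated
#' with the test labels. Per-individual posteriors are the fractions of
#' post-burn-in sweeps spent in each class.
#'
#' @param geno test individuals x loci genotype matrix aligned to
#'   `ref_panel`'s loci.
#' @param ref_panel a `ref_panel` of known-origin reference individuals.
#' @param n_burnin burn-in sweeps (default 10000).
#' @param n_sweeps retained sweeps (default 50000).
#' @param seed integer seed; results are reproducible given the seed.
#' @return data frame as [assign_plugin()].
#' @export
assign_gibbs <- function(geno, ref_panel, n_burnin = 10000L,
                         n_sweeps = 50000L, seed = 1L) {
  stopifnot(inherits(ref_panel, "ref_panel"))
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  if (ncol(geno) != ncol(ref_panel$geno)) {
    stop_param("test matrix and reference panel disagree on loci")
  }
  check_genotype_codes(geno)
  set.seed(seed)
  sp <- split_populations(ref_panel)
  beta_par <- function(g) {
    n_called <- colSums(!is.na(g))
    alt <- colSums(g, na.rm = TRUE)
    list(a = alt + 0.5, b = 2 * n_called - alt + 0.5)
  }
  b0 <- beta_par(sp$g0)
  b1 <- beta_par(sp$g1)

  n <- nrow(geno)
  L <- ncol(geno)
  ind <- lapply(0:2, function(v) {
    m <- (!is.na(geno)) & geno == v
    storage.mode(m) <- "double"
    m
  })

  counts <- matrix(0, n, 6)
  pi_now <- rep(1 / 6, 6)
  upper_tri_ones <- outer(1:6, 1:6, `<=`) * 1
  total <- n_burnin + n_sweeps
  for (it in seq_len(total)) {
    p0 <- rbeta(L, b0$a, b0$b)
    p1 <- rbeta(L, b1$a, b1$b)
    lp <- class_loglik_tables(p0, p1)
    ll <- ind[[1]] %*% lp$g0 + ind[[2]] %*% lp$g1 + ind[[3]] %*% lp$g2
    w <- normalize_posterior(ll, log(pi_now))
    # sample one class per individual from its row of w; cumulative
    # probabilities via matrix product with an upper-triangular 1s matrix
    cm <- w %*% upper_tri_ones
    cm[, 6] <- 1
    u <- runif(n)
    z <- max.col(u < cm, ties.method = "first")
    if (it > n_burnin) counts[cbind(seq_len(n), z)] <-
        counts[cbind(seq_len(n), z)] + 1
    tab <- tabulate(z, nbins = 6)
    gam <- rgamma(6, shape = tab + 1)
    pi_now <- gam / sum(gam)
  }
  post <- counts / n_sweeps
  ids <- rownames(geno) %||% sprintf("ind_%04d", seq_len(nrow(geno)))
  assignment_frame(post, rowSums(!is.na(geno)), ids)
}
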