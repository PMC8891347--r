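make_freqs <- function(p0, p1) {
  structure(list(p0 = p0, p1 = p1,
                 n_called0 = rep(10L, length(p0)),
                 n_called1 = rep(10L, length(p0)),
                 uninformative = rep(FALSE, length(p0)),
                 locus_id = sprintf("L%03d", seq_along(p0)),
                 pseudocount = 0.5), class = "ref_freqs")
}

test_that("reference frequency smoothing follows the pseudocount formula", {
  g0 <- matrix(0L, nrow = 20, ncol = 1)  # 0 alt alleles of 40
  g1 <- matrix(2L, nrow = 20, ncol = 1)
  panel <- make_ref_panel(g0, g1)
  fr <- estimate_reference_frequencies(panel, pseudocount = 0.5)
  expect_equal(fr$p0, 0.5 / 41, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fr$p1, 40.5 / 41, tolerance = 1e-12, ignore_attr = TRUE)

  # pseudocount 0 returns the plain sample frequency
  g0 <- matrix(c(0L, 1L, 1L, 2L), ncol = 1)
  g1 <- matrix(c(0L, 0L, 1L, 1L), ncol = 1)
  fr <- estimate_reference_frequencies(make_ref_panel(g0, g1), pseudocount = 0)
  expect_equal(unname(fr$p0), 0.5)
  expect_equal(unname(fr$p1), 0.25)

  # all-missing locus in one population: frequency 0.5 and flagged
  g0 <- matrix(NA_integer_, nrow = 4, ncol = 1)
  g1 <- matrix(c(0L, 1L, 2L, 1L), ncol = 1)
  fr <- estimate_reference_frequencies(make_ref_panel(g0, g1))
  expect_equal(unname(fr$p0), 0.5)
  expect_true(fr$uninformative[1])
})

test_that("class genotype probabilities sum to one and match enumeration", {
  grid <- expand.grid(p0 = c(0.05, 0.3, 0.5, 0.9), p1 = c(0.1, 0.45, 0.95))
  for (cl in CLASSES) {
    phi <- class_phi(cl)
    pr <- class_genotype_prob(phi, grid$p0, grid$p1)
    expect_equal(rowSums(pr), rep(1, nrow(grid)), tolerance = 1e-12)
    for (i in seq_len(nrow(grid))) {
      expect_equal(unname(pr[i, ]),
                   unname(genotype_prob_oracle(phi, grid$p0[i], grid$p1[i])),
                   tolerance = 1e-12,
                   label = sprintf("%s at (%g, %g)", cl, grid$p0[i], grid$p1[i]))
    }
  }
})

test_that("limiting cases of the genotype-class model behave as expected", {
  # F2 at p0 = p1 = 0.5 is plain HWE at 0.5
  pr <- class_genotype_prob(class_phi("F2"), 0.5, 0.5)
  expect_equal(unname(pr[1, ]), c(0.25, 0.5, 0.25))
  # F1 at a nearly diagnostic locus is almost surely heterozygous
  pr <- class_genotype_prob(class_phi("F1"), 1 - 1e-6, 1e-6)
  expect_gt(pr[1, "g1"], 0.999)
  expect_error(class_genotype_prob(class_phi("F1"), 0, 0.5), "strictly inside")
})

test_that("plug-in posteriors match a brute-force three-locus oracle", {
  fr <- make_freqs(c(0.9, 0.2, 0.6), c(0.1, 0.7, 0.3))
  geno <- rbind(c(2L, 0L, 1L), c(1L, 1L, NA), c(0L, 2L, 2L))
  res <- assign_plugin(geno, fr)

  classes <- hybrid_classes()
  for (i in 1:3) {
    lik <- vapply(seq_len(6), function(k) {
      phi <- unlist(classes[k, c("phi00", "phi01", "phi11")])
      l <- 1
      for (j in 1:3) {
        g <- geno[i, j]
        if (is.na(g)) next
        pr <- genotype_prob_oracle(phi, fr$p0[j], fr$p1[j])
        l <- l * pr[g + 1]
      }
      l
    }, numeric(1))
    post <- lik / sum(lik)
    got <- unlist(res[i, paste0("post_", CLASSES)])
    expect_equal(unname(got), unname(post), tolerance = 1e-12)
  }
  expect_equal(res$loci_used, c(3, 2, 3))
})

test_that("diagnostic panels give near-certain plug-in assignments", {
  L <- 100
  fr <- make_freqs(rep(0.99, L), rep(0.01, L))
  het <- matrix(1L, 1, L)
  res <- assign_plugin(het, fr)
  expect_equal(res$max_class, "F1")
  expect_gt(res$max_posterior, 0.999)

  hom <- matrix(2L, 1, L)
  res <- assign_plugin(hom, fr)
  expect_equal(res$max_class, "pure0")
  expect_gt(res$max_posterior, 0.999)
})

test_that("posteriors normalize, ignore uninformative loci, and flag no-data individuals", {
  set.seed(31)
  L <- 30
  fr <- make_freqs(runif(L, 0.6, 0.95), runif(L, 0.05, 0.4))
  geno <- simulate_cohort(fr$p0, fr$p1,
                          c(pure0 = 5, F1 = 5, BC1 = 5), seed = 1)$geno
  res <- assign_plugin(geno, fr)
  post <- as.matrix(res[, paste0("post_", CLASSES)])
  expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-9)

  # an added locus with p0 = p1 changes nothing
  fr2 <- make_freqs(c(fr$p0, 0.42), c(fr$p1, 0.42))
  geno2 <- cbind(geno, 1L)
  res2 <- assign_plugin(geno2, fr2)
  expect_equal(as.matrix(res2[, paste0("post_", CLASSES)]), post,
               tolerance = 1e-12)

  # all-missing individual: prior returned, tie flagged
  res3 <- assign_plugin(matrix(NA_integer_, 1, L), fr)
  expect_equal(unlist(res3[1, paste0("post_", CLASSES)]),
               setNames(rep(1 / 6, 6), paste0("post_", CLASSES)),
               tolerance = 1e-12)
  expect_true(res3$tie)
  expect_equal(res3$loci_used, 0)
})

test_that("label swap permutes plug-in posteriors exactly", {
  set.seed(17)
  L <- 40
  p0 <- runif(L, 0.5, 0.95)
  p1 <- runif(L, 0.05, 0.5)
  geno <- simulate_cohort(p0, p1, c(F2 = 4, BC0 = 4, pure1 = 4), seed = 2)$geno
  a <- assign_plugin(geno, make_freqs(p0, p1))
  b <- assign_plugin(geno, make_freqs(p1, p0))
  perm <- c(post_pure0 = "post_pure1", post_pure1 = "post_pure0",
            post_F1 = "post_F1", post_F2 = "post_F2",
            post_BC0 = "post_BC1", post_BC1 = "post_BC0")
  for (col in names(perm)) {
    expect_equal(a[[col]], b[[perm[[col]]]], tolerance = 1e-9)
  }
})

test_that("Gibbs assignment is seeded-reproducible and matches the plug-in mode", {
  set.seed(23)
  L <- 80
  g0 <- matrix(rbinom(12 * L, 2, rep(runif(L, 0.75, 0.99), each = 12)),
               nrow = 12)
  g1 <- matrix(rbinom(15 * L, 2, rep(runif(L, 0.01, 0.25), each = 15)),
               nrow = 15)
  ref <- make_ref_panel(g0, g1)
  fr <- estimate_reference_frequencies(ref)
  sim <- simulate_cohort(fr$p0, fr$p1,
                         setNames(rep(8, 6), CLASSES), seed = 3)
  gb1 <- assign_gibbs(sim$geno, ref, n_burnin = 300, n_sweeps = 1500, seed = 5)
  gb2 <- assign_gibbs(sim$geno, ref, n_burnin = 300, n_sweeps = 1500, seed = 5)
  expect_identical(gb1, gb2)

  # strongly differentiated panel: Gibbs agrees with the plug-in mode
  plug <- assign_plugin(sim$geno, fr)
  agree <- mean(gb1$max_class == plug$max_class)
  expect_gte(agree, 0.95)
  f1 <- which(sim$labels == "F1")
  expect_true(all(gb1$post_F1[f1] >= 0.95))
  post <- as.matrix(gb1[, paste0("post_", CLASSES)])
  expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-9)

  # fully diagnostic references: an obligate-heterozygote F1 is pinned
  dref <- make_ref_panel(matrix(2L, 10, 40), matrix(0L, 12, 40))
  dgb <- assign_gibbs(matrix(1L, 1, 40), dref,
                      n_burnin = 300, n_sweeps = 1500, seed = 6)
  expect_equal(dgb$max_class, "F1")
  expect_gte(dgb$post_F1, 0.99)
})
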