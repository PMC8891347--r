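test_that("individual missingness filter uses a strict 25% boundary", {
  L <- 342
  geno <- matrix(1L, nrow = 3, ncol = L)
  geno[2, 1:85] <- NA    # 85/342 = 24.9% -> kept
  geno[3, 1:86] <- NA    # 86/342 = 25.1% -> removed
  res <- filter_individuals_by_missingness(geno, max_missing = 0.25)
  expect_equal(res$kept, c(TRUE, TRUE, FALSE))
  expect_equal(nrow(res$geno), 2)

  # a cohort of 218 with 16 planted high-missing fish leaves 202
  set.seed(51)
  geno <- matrix(sample(0:2, 218 * 100, replace = TRUE), nrow = 218)
  high <- sample(218, 16)
  geno[high, 1:40] <- NA   # 40% missing
  res <- filter_individuals_by_missingness(geno)
  expect_equal(nrow(res$geno), 202)
})

test_that("stock composition reproduces the 2019 spawner arithmetic", {
  counts <- c(pure0 = 115, BC0 = 24, F1 = 16, F2 = 4, BC1 = 19, pure1 = 24)
  hs <- hybrid_summary(counts)
  expect_equal(hs$n, 202)
  expect_equal(round(hs$hybrid_fraction, 2), 0.31)
  expect_equal(hs$advanced_fraction, 47 / 63, tolerance = 1e-12)
  expect_lt(abs(100 * hs$advanced_fraction - 74), 1)  # "~74%" of hybrids
  expect_equal(round(unname(hs$proportions["pure0"]), 2), 0.57)
  expect_equal(round(unname(hs$proportions["pure1"]), 2), 0.12)

  # per-individual route gives the same table
  classes <- rep(names(counts), counts)
  comp <- stock_composition(classes, rep(2019, 202))
  expect_equal(unname(comp$n), 202)
  expect_equal(unname(comp$hybrid_fraction), hs$hybrid_fraction)
  expect_equal(unname(rowSums(comp$proportions)), 1)

  # the 2016 composition: 16/1/8/0/0/11
  c2016 <- c(pure0 = 16, BC0 = 1, F1 = 8, F2 = 0, BC1 = 0, pure1 = 11)
  hs16 <- hybrid_summary(c2016)
  expect_equal(round(unname(hs16$proportions[CLASSES]), 2),
               c(0.44, 0.31, 0.22, 0.00, 0.03, 0.00))

  # all-resident cohort has no hybrids
  hs0 <- hybrid_summary(c(pure0 = 30))
  expect_equal(hs0$hybrid_fraction, 0)
  expect_true(is.na(hs0$advanced_fraction))
})

test_that("within-year class test is Pearson goodness-of-fit against equality", {
  r <- within_year_class_test(rep(10, 6))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df, 5)

  # 2019 counts: chi2 from the definition sum((o - e)^2 / e)
  counts <- c(115, 24, 16, 4, 19, 24)
  e <- sum(counts) / 6
  expect_equal(within_year_class_test(counts)$chi2,
               sum((counts - e)^2 / e), tolerance = 1e-12)
  expect_equal(round(within_year_class_test(counts)$chi2, 1), 243.8)

  # single occupied class: chi2 = 5n
  for (n in c(6, 60)) {
    expect_equal(within_year_class_test(c(n, 0, 0, 0, 0, 0))$chi2, 5 * n)
  }

  r <- within_year_class_test(counts, simulate_p = TRUE, n_sim = 2000,
                              seed = 3)
  expect_lt(r$p_exact, 0.01)
})

test_that("across-year class test matches the textbook 2x2 chi-square", {
  r <- across_year_class_test(c(10, 20), c(50, 100))
  expect_lt(r$chi2, 1e-12)

  r <- across_year_class_test(c(11, 18, 24), c(36, 55, 202))
  expect_equal(r$df, 2)

  # hand-computed 2x2 without continuity correction
  tab <- rbind(c(12, 30), c(28, 50))
  n <- sum(tab)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / n
  hand <- sum((tab - exp_tab)^2 / exp_tab)
  got <- across_year_class_test(class_counts = tab[1, ],
                                totals = colSums(tab))
  expect_equal(got$chi2, hand, tolerance = 1e-12)

  expect_error(across_year_class_test(c(5), c(10)), "two years")
  expect_error(across_year_class_test(c(5, 60), c(10, 50)), "exceed")
})

test_that("fork-length ANOVA matches an explicit sums-of-squares oracle", {
  # identical groups: no signal
  r <- fork_length_comparison(c(30, 31, 32, 30, 31, 32),
                              rep(c("pure0", "pure1"), each = 3))
  expect_lt(r$anova_F, 1e-20)

  # kokanee ~26 cm vs sockeye >45 cm separates decisively
  set.seed(61)
  lengths <- c(rnorm(20, 26, 1.5), rnorm(20, 47, 2))
  classes <- rep(c("pure0", "pure1"), each = 20)
  r <- fork_length_comparison(lengths, classes)
  expect_lt(r$p, 1e-10)
  expect_equal(nrow(r$tukey), 1)
  expect_lt(r$tukey$p_adj, 0.001)

  # three groups against the ANOVA identity
  set.seed(62)
  g <- rep(c("pure0", "F1", "pure1"), times = c(12, 9, 14))
  y <- rnorm(35, mean = c(pure0 = 26, F1 = 35, pure1 = 47)[g], sd = 3)
  r <- fork_length_comparison(y, g)
  grand <- mean(y)
  ss_between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  F_oracle <- (ss_between / 2) / (ss_within / (35 - 3))
  expect_equal(r$anova_F, F_oracle, tolerance = 1e-10)
  expect_equal(r$df, c(2, 32))

  expect_error(fork_length_comparison(1:4, c("a", "a", "a", "b")),
               "two groups")
})
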