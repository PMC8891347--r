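test_that("quality filters apply the call-rate and strict-MAF boundaries", {
  stats <- rbind(
    stats_row("L001", call0 = 0.59, call1 = 0.95),          # call-rate fail
    stats_row("L002", call0 = 0.60, call1 = 0.60),          # boundary kept
    stats_row("L003", maf = 0.05),                          # MAF == 0.05 fails
    stats_row("L004", maf = 0.051),
    stats_row("L005")
  )
  res <- apply_quality_filters(stats, filter_config())
  expect_setequal(res$kept$locus_id, c("L002", "L004", "L005"))
  expect_equal(unname(res$reasons["L001"]), "call_rate")
  expect_equal(unname(res$reasons["L003"]), "maf")
  expect_equal(res$report$n_in, 5)
  expect_equal(res$report$n_out, 3)
})

test_that("a fixture with a known failing fraction survives as constructed", {
  rows <- lapply(1:100, function(i) {
    if (i <= 10) stats_row(sprintf("L%03d", i), call0 = 0.4)
    else stats_row(sprintf("L%03d", i))
  })
  stats <- do.call(rbind, rows)
  res <- apply_quality_filters(stats)
  expect_equal(nrow(res$kept), 90)
})

test_that("homeolog filter needs the signature in both populations", {
  stats <- rbind(
    stats_row("H1", hobs0 = 1.0, hobs1 = 1.0),              # removed
    stats_row("H2", fis0 = -0.2, fis1 = 0.3, hobs0 = 0.4, hobs1 = 0.4),
    stats_row("H3", fis0 = -0.1, fis1 = -0.1),              # removed
    stats_row("H4", fis0 = NA, fis_def0 = FALSE, fis1 = -0.5, hobs0 = 0)
  )
  res <- homeolog_filter(stats, filter_config())
  expect_setequal(res$kept$locus_id, c("H2", "H4"))
  expect_true("H4" %in% res$flagged_undefined)
  expect_equal(unname(res$reasons["H1"]), "homeolog")
})

test_that("HWE filter removes failure in either population; alpha 0 disables", {
  stats <- rbind(
    stats_row("W1", hwe0 = 0.001, hwe1 = 0.8),
    stats_row("W2", hwe0 = 0.5, hwe1 = 0.5),
    stats_row("W3", hwe0 = 0.9, hwe1 = 0.01)
  )
  res <- hwe_filter(stats, filter_config(hwe_alpha = 0.05))
  expect_equal(res$kept$locus_id, "W2")
  res0 <- hwe_filter(stats, filter_config(hwe_alpha = 0))
  expect_equal(nrow(res0$kept), 3)
})

test_that("position window is inclusive and ranking takes the exact top set", {
  stats <- rbind(
    stats_row("P39", snp_pos = 39L, theta = 0.9),
    stats_row("P40", snp_pos = 40L, theta = 0.8),
    stats_row("P70", snp_pos = 70L, theta = 0.7),
    stats_row("P71", snp_pos = 71L, theta = 0.95)
  )
  res <- suppressWarnings(position_and_rank(stats, filter_config(top_n_fst = 10L)))
  expect_setequal(res$kept$locus_id, c("P40", "P70"))
  expect_equal(unname(res$reasons["P39"]), "position")

  # 1000 distinct thetas: output is exactly the 650 largest, ordered
  set.seed(1)
  theta <- sample(seq(0.001, 0.999, length.out = 1000))
  rows <- lapply(1:1000, function(i) {
    stats_row(sprintf("T%04d", i), theta = theta[i])
  })
  stats <- do.call(rbind, rows)
  res <- position_and_rank(stats, filter_config(top_n_fst = 650L))
  expect_equal(nrow(res$kept), 650)
  expect_equal(sort(res$kept$theta, decreasing = TRUE),
               sort(theta, decreasing = TRUE)[1:650])
  expect_false(res$ties)

  # tie at the cutoff: deterministic lexicographic break, flagged
  stats <- rbind(
    stats_row("A1", theta = 0.9), stats_row("A3", theta = 0.5),
    stats_row("A2", theta = 0.5)
  )
  res <- position_and_rank(stats, filter_config(top_n_fst = 2L))
  expect_equal(res$kept$locus_id, c("A1", "A2"))
  expect_true(res$ties)
})

test_that("fewer loci than top_n_fst warns and returns all", {
  stats <- rbind(stats_row("S1"), stats_row("S2"))
  expect_warning(res <- position_and_rank(stats, filter_config()),
                 "fewer loci")
  expect_equal(nrow(res$kept), 2)
})

test_that("ld_prune removes the lower-theta member of a planted duplicate", {
  set.seed(11)
  L <- 12
  n0 <- 20; n1 <- 20
  g0 <- matrix(rbinom(n0 * L, 2, 0.5), nrow = n0)
  g1 <- matrix(rbinom(n1 * L, 2, 0.5), nrow = n1)
  g0[, 2] <- g0[, 1]; g1[, 2] <- g1[, 1]  # exact duplicate pair L001/L002
  panel <- make_ref_panel(g0, g1)
  theta <- c(0.8, 0.7, runif(L - 2, 0.1, 0.6))
  cand <- do.call(rbind, lapply(seq_len(L), function(i) {
    stats_row(sprintf("L%03d", i), theta = theta[i])
  }))
  cand <- cand[order(-cand$theta), ]
  res <- ld_prune(cand, panel$geno, filter_config(n_candidates = 20L),
                  seed = 3, pop = panel$pop)
  expect_false("L002" %in% res$kept$locus_id)   # the lower-theta duplicate
  expect_true("L001" %in% res$kept$locus_id)
  expect_equal(unname(res$reasons["L002"]), "linkage")
})

test_that("independent loci survive pruning and truncation caps the panel", {
  set.seed(12)
  L <- 30
  g0 <- matrix(rbinom(25 * L, 2, 0.5), nrow = 25)
  g1 <- matrix(rbinom(25 * L, 2, 0.5), nrow = 25)
  panel <- make_ref_panel(g0, g1)
  cand <- do.call(rbind, lapply(seq_len(L), function(i) {
    stats_row(sprintf("L%03d", i), theta = 1 - i / 100)
  }))
  res <- ld_prune(cand, panel$geno, filter_config(n_candidates = 600L),
                  seed = 4, pop = panel$pop)
  expect_equal(nrow(res$kept), L)

  res <- ld_prune(cand, panel$geno, filter_config(n_candidates = 20L),
                  seed = 4, pop = panel$pop)
  expect_equal(nrow(res$kept), 20)
  # truncation keeps the highest-theta survivors
  expect_equal(res$kept$locus_id, cand$locus_id[1:20])
})

test_that("primer-dropout modes behave and validate", {
  cand <- do.call(rbind, lapply(1:600, function(i) {
    stats_row(sprintf("L%04d", i), theta = 1 - i / 1000)
  }))
  r1 <- model_primer_dropout(cand, "random_subset", list(k = 350), seed = 9)
  r2 <- model_primer_dropout(cand, "random_subset", list(k = 350), seed = 9)
  expect_equal(nrow(r1), 350)
  expect_identical(r1, r2)
  expect_error(model_primer_dropout(cand, "random_subset", list(k = 700)),
               "panel size")

  shares <- setNames(rep(0.001, 600), cand$locus_id)
  shares["L0007"] <- 0.03
  rs <- model_primer_dropout(cand, "read_share",
                             list(read_share = shares, max_share = 0.02))
  expect_false("L0007" %in% rs$locus_id)
  expect_equal(nrow(rs), 599)
  # exactly 2% is not "greater than 2%"
  shares["L0007"] <- 0.02
  rs <- model_primer_dropout(cand, "read_share",
                             list(read_share = shares, max_share = 0.02))
  expect_equal(nrow(rs), 600)

  dl <- model_primer_dropout(cand, "drop_list",
                             list(drop = cand$locus_id[1:258]))
  expect_equal(nrow(dl), 342)
  expect_error(model_primer_dropout(cand, "drop_list", list(drop = "nope")),
               "unknown loci")
})

test_that("the full chain conserves counts and is seed-deterministic", {
  model <- population_model(n_loci = 700, n_pop0 = 15, n_pop1 = 18,
                            n_linked_pairs = 8, n_homeolog_like = 12,
                            seed = 21)
  panel <- simulate_rad_dataset(model)
  des1 <- suppressWarnings(design_panel(panel, seed = 5))
  des2 <- suppressWarnings(design_panel(panel, seed = 5))
  expect_identical(des1$candidates, des2$candidates)

  rep <- des1$report
  expect_equal(rep$n_in - rep$n_removed, rep$n_out)
  # each stage's survivors enter the next stage
  expect_equal(rep$n_out[-nrow(rep)], rep$n_in[-1])
  expect_equal(rep$n_in[1], 700)
  expect_equal(rep$n_out[nrow(rep)], nrow(des1$candidates))

  # removal reasons are unique per locus and account for every removal
  removed <- setdiff(des1$stats$locus_id, des1$candidates$locus_id)
  expect_setequal(names(des1$reasons), removed)

  # forced all-het homeolog loci never reach the candidate list
  hom <- panel$loci$locus_id[panel$loci$type == "homeolog"]
  expect_length(intersect(hom, des1$candidates$locus_id), 0)
})
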