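#' Configuration of the candidate-locus filter chain
#'
#' Holds the thresholds of the panel design filter chain. Defaults follow
#' the workflow the package models: loci must be called in at least 60% of
#' individuals in both reference populations with pooled minor allele
#' frequency strictly greater than 0.05; suspected homeologs (negative Fis
#' or observed heterozygosity above 0.5 in both populations) are removed;
#' loci out of Hardy-Weinberg equilibrium in either population at
#' `hwe_alpha` are removed; the SNP must sit between the 40th and 70th base
#' pair of its RAD tag (inclusive); the 650 highest-theta loci are carried
#' into linkage pruning, which yields `n_candidates = 600` final candidates.
#'
#' @param min_call_rate minimum per-population call rate (kept when
#'   `>=` in both populations).
#' @param min_maf pooled minor-allele-frequency floor (kept when strictly
#'   greater).
#' @param homeolog_hobs_max observed-heterozygosity ceiling of the homeolog
#'   screen.
#' @param hwe_alpha per-population HWE exact-test significance level;
#'   `0` disables the filter.
#' @param position_window inclusive 1-based SNP position window within the
#'   RAD tag.
#' @param top_n_fst number of top-theta loci retained before linkage
#'   pruning.
#' @param ld_alpha significance level of the pairwise linkage permutation
#'   test.
#' @param ld_n_permutations permutations per linkage test.
#' @param ld_prescreen_r2 minimum pairwise genotype r-squared for a pair to
#'   be permutation-tested (screens the quadratic number of pairs down to
#'   those that could plausibly be linked).
#' @param n_candidates final candidate-panel size after pruning.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_call_rate = 0.60,
                          min_maf = 0.05,
                          homeolog_hobs_max = 0.5,
                          hwe_alpha = 0.05,
                          position_window = c(40L, 70L),
                          top_n_fst = 650L,
                          ld_alpha = 0.05,
                          ld_n_permutations = 999L,
                          ld_prescreen_r2 = 0.8,
                          n_candidates = 600L) {
  cfg <- list(min_call_rate = min_call_rate, min_maf = min_maf,
              homeolog_hobs_max = homeolog_hobs_max, hwe_alpha = hwe_alpha,
              position_window = as.integer(position_window),
              top_n_fst = as.integer(top_n_fst),
              ld_alpha = ld_alpha,
              ld_n_permutations = as.integer(ld_n_permutations),
              ld_prescreen_r2 = ld_prescreen_r2,
              n_candidates = as.integer(n_candidates))
  if (!(cfg$min_call_rate > 0 && cfg$min_call_rate <= 1)) {
    stop_param("min_call_rate must be in (0, 1]")
  }
  if (length(cfg$position_window) != 2 ||
      cfg$position_window[1] < 1 ||
      cfg$position_window[1] > cfg$position_window[2]) {
    stop_param("position_window must be an increasing pair with lower end >= 1")
  }
  class(cfg) <- "filter_config"
  cfg
}

new_filter_report <- function() {
  data.frame(stage = character(0), n_in = integer(0),
             n_removed = integer(0), n_out = integer(0),
             stringsAsFactors = FALSE)
}

add_stage <- function(report, stage, n_in, n_out) {
  rbind(report, data.frame(stage = stage, n_in = n_in,
                           n_removed = n_in - n_out, n_out = n_out,
                           stringsAsFactors = FALSE))
}

#' Call-rate and minor-allele-frequency filters
#'
#' Keeps loci called in at least `min_call_rate` of individuals in both
#' populations and with pooled minor allele frequency strictly greater
#' than `min_maf`.
#'
#' @param stats locus statistics table from [locus_stats_table()].
#' @param config a [filter_config()].
#' @return list with `kept` (surviving rows of `stats`), `report`
#'   (stage-count data frame), and `reasons` (named character vector,
#'   first removal reason per removed locus).
#' @export
apply_quality_filters <- function(stats, config = filter_config()) {
  ok_call <- stats$call_rate_pop0 >= config$min_call_rate &
    stats$call_rate_pop1 >= config$min_call_rate
  ok_maf <- !is.na(stats$maf_pooled) & stats$maf_pooled > config$min_maf
  reasons <- character(0)
  reasons[stats$locus_id[!ok_call]] <- "call_rate"
  reasons[stats$locus_id[ok_call & !ok_maf]] <- "maf"
  keep <- ok_call & ok_maf
  report <- add_stage(new_filter_report(), "quality", nrow(stats), sum(keep))
  list(kept = stats[keep, , drop = FALSE], report = report, reasons = reasons)
}

#' Homeolog (heterozygosity-excess) filter
#'
#' Removes a locus only when the homeolog signature — negative Fis or
#' observed heterozygosity above `homeolog_hobs_max` — is present in BOTH
#' reference populations, the pattern expected of collapsed salmonid
#' paralogs rather than population-specific inbreeding artefacts. A
#' population with undefined Fis (monomorphic) counts as not showing the
#' signature, so such loci are conservatively kept and flagged.
#'
#' @inheritParams apply_quality_filters
#' @return as [apply_quality_filters()], plus `flagged_undefined`: ids of
#'   kept loci where Fis was undefined in a population.
#' @export
homeolog_filter <- function(stats, config = filter_config()) {
  sig <- function(fis, fis_def, hobs) {
    (fis_def & !is.na(fis) & fis < 0) | (!is.na(hobs) & hobs > config$homeolog_hobs_max)
  }
  s0 <- sig(stats$fis_pop0, stats$fis_defined_pop0, stats$hobs_pop0)
  s1 <- sig(stats$fis_pop1, stats$fis_defined_pop1, stats$hobs_pop1)
  remove <- s0 & s1
  reasons <- character(0)
  reasons[stats$locus_id[remove]] <- "homeolog"
  report <- add_stage(new_filter_report(), "homeolog", nrow(stats), sum(!remove))
  flagged <- stats$locus_id[!remove &
                              (!stats$fis_defined_pop0 | !stats$fis_defined_pop1)]
  list(kept = stats[!remove, , drop = FALSE], report = report,
       reasons = reasons, flagged_undefined = flagged)
}

#' Hardy-Weinberg equilibrium filter
#'
#' Removes loci whose exact HWE p-value falls below `hwe_alpha` in either
#' population. `hwe_alpha = 0` disables the filter.
#'
#' @inheritParams apply_quality_filters
#' @export
hwe_filter <- function(stats, config = filter_config()) {
  fail <- (!is.na(stats$hwe_p_pop0) & stats$hwe_p_pop0 < config$hwe_alpha) |
    (!is.na(stats$hwe_p_pop1) & stats$hwe_p_pop1 < config$hwe_alpha)
  reasons <- character(0)
  reasons[stats$locus_id[fail]] <- "hwe"
  report <- add_stage(new_filter_report(), "hwe", nrow(stats), sum(!fail))
  list(kept = stats[!fail, , drop = FALSE], report = report, reasons = reasons)
}

#' Tag-position filter and theta ranking
#'
#' Keeps loci whose SNP sits inside the inclusive `position_window` of the
#' RAD tag (so flanking sequence suffices for primer design), sorts the
#' survivors by Weir-Cockerham theta descending, and truncates to
#' `top_n_fst`. Theta ties are broken lexicographically by locus id and
#' flagged.
#'
#' @inheritParams apply_quality_filters
#' @return list with `kept` (ordered data frame), `report`, `reasons`, and
#'   `ties` (logical: were there theta ties anywhere in the ranking).
#' @export
position_and_rank <- function(stats, config = filter_config()) {
  in_window <- stats$snp_pos >= config$position_window[1] &
    stats$snp_pos <= config$position_window[2]
  reasons <- character(0)
  reasons[stats$locus_id[!in_window]] <- "position"
  windowed <- stats[in_window, , drop = FALSE]
  windowed <- windowed[!is.na(windowed$theta), , drop = FALSE]
  n_pos <- nrow(windowed)
  ord <- order(-windowed$theta, windowed$locus_id)
  windowed <- windowed[ord, , drop = FALSE]
  ties <- anyDuplicated(windowed$theta) > 0
  if (n_pos < config$top_n_fst) {
    warning("fewer loci (", n_pos, ") than top_n_fst (", config$top_n_fst,
            "); returning all", call. = FALSE)
    kept <- windowed
  } else {
    kept <- windowed[seq_len(config$top_n_fst), , drop = FALSE]
    reasons[windowed$locus_id[-seq_len(config$top_n_fst)]] <- "fst_rank"
  }
  report <- add_stage(new_filter_report(), "position", nrow(stats), n_pos)
  report <- add_stage(report, "fst_rank", n_pos, nrow(kept))
  list(kept = kept, report = report, reasons = reasons, ties = ties)
}

#' Linkage pruning of the ranked candidates
#'
#' Tests candidate pairs for genotypic linkage disequilibrium and, for
#' every significant pair, removes the lower-theta member, repeating until
#' no significant pair survives; the result is truncated to `n_candidates`
#' by theta rank. When a population factor is supplied, each pair is
#' tested within each population and the p-values are combined with
#' Fisher's method — testing on the pooled sample would confound physical
#' linkage with population structure and preferentially strip the most
#' differentiated (most informative) loci. Pairs are prescreened by
#' within-population genotype correlation (`max r^2 >= ld_prescreen_r2`)
#' before the permutation G-test is run, which keeps the quadratic pair
#' scan tractable and avoids stripping the panel on chance significance
#' across ~200k independent pairs.
#'
#' @param candidates ranked candidate table from [position_and_rank()].
#' @param geno full individuals x loci genotype matrix (column names are
#'   locus ids).
#' @param config a [filter_config()].
#' @param seed integer seed for the permutation tests.
#' @param pop optional factor splitting the rows of `geno` into the two
#'   reference populations; `NULL` tests on the pooled sample.
#' @return list with `kept` (pruned, truncated table), `report`, `reasons`,
#'   and `tested_pairs` (data frame of prescreened pairs with p-values).
#' @export
ld_prune <- function(candidates, geno, config = filter_config(), seed = 1L,
                     pop = NULL) {
  stopifnot(all(candidates$locus_id %in% colnames(geno)))
  ids <- candidates$locus_id
  groups <- if (is.null(pop)) {
    list(geno[, ids, drop = FALSE])
  } else {
    stopifnot(length(pop) == nrow(geno))
    lapply(split(seq_len(nrow(geno)), pop),
           function(i) geno[i, ids, drop = FALSE])
  }
  # prescreen: squared pairwise correlation of genotype dosages, within
  # population; a pair is tested if correlated in any population
  r2 <- matrix(0, length(ids), length(ids))
  for (g in groups) {
    suppressWarnings(cmat <- cor(g, use = "pairwise.complete.obs"))
    cmat[is.na(cmat)] <- 0
    r2 <- pmax(r2, cmat^2)
  }
  cand_pairs <- which(upper.tri(r2) & r2 >= config$ld_prescreen_r2,
                      arr.ind = TRUE)
  tested <- data.frame(locus_a = character(0), locus_b = character(0),
                       p = numeric(0), stringsAsFactors = FALSE)
  if (nrow(cand_pairs)) {
    # deterministic pair order, one seeded test per pair and population;
    # per-population p-values combined by Fisher's method
    cand_pairs <- cand_pairs[order(cand_pairs[, 1], cand_pairs[, 2]), ,
                             drop = FALSE]
    set.seed(seed)
    pair_seeds <- matrix(sample.int(.Machine$integer.max,
                                    nrow(cand_pairs) * length(groups)),
                         ncol = length(groups))
    p <- vapply(seq_len(nrow(cand_pairs)), function(k) {
      pk <- vapply(seq_along(groups), function(gi) {
        ld_genotypic_test(groups[[gi]][, cand_pairs[k, 1]],
                          groups[[gi]][, cand_pairs[k, 2]],
                          n_permutations = config$ld_n_permutations,
                          seed = pair_seeds[k, gi])$p
      }, numeric(1))
      if (length(pk) == 1) pk else {
        pchisq(-2 * sum(log(pk)), df = 2 * length(pk), lower.tail = FALSE)
      }
    }, numeric(1))
    tested <- data.frame(locus_a = ids[cand_pairs[, 1]],
                         locus_b = ids[cand_pairs[, 2]],
                         p = p, stringsAsFactors = FALSE)
  }

  theta <- setNames(candidates$theta, ids)
  alive <- setNames(rep(TRUE, length(ids)), ids)
  reasons <- character(0)
  sig <- tested[tested$p < config$ld_alpha, , drop = FALSE]
  if (nrow(sig)) {
    sig <- sig[order(sig$p, sig$locus_a, sig$locus_b), , drop = FALSE]
    repeat {
      live <- alive[sig$locus_a] & alive[sig$locus_b]
      if (!any(live)) break
      pair <- sig[which(live)[1], ]
      # remove the lower-theta member; theta ties fall to the later id
      drop_id <- if (theta[pair$locus_a] < theta[pair$locus_b] ||
                     (theta[pair$locus_a] == theta[pair$locus_b] &&
                      pair$locus_a > pair$locus_b)) pair$locus_a else pair$locus_b
      alive[drop_id] <- FALSE
      reasons[drop_id] <- "linkage"
    }
  }
  pruned <- candidates[alive[candidates$locus_id], , drop = FALSE]
  n_after_ld <- nrow(pruned)
  if (n_after_ld > config$n_candidates) {
    reasons[pruned$locus_id[-seq_len(config$n_candidates)]] <- "candidate_cap"
    pruned <- pruned[seq_len(config$n_candidates), , drop = FALSE]
  }
  report <- add_stage(new_filter_report(), "ld_prune", nrow(candidates),
                      n_after_ld)
  report <- add_stage(report, "candidate_cap", n_after_ld, nrow(pruned))
  list(kept = pruned, report = report, reasons = reasons,
       tested_pairs = tested)
}

#' Model primer dropout during multiplex optimization
#'
#' The wet-lab optimization of a multiplex amplicon panel loses loci to
#' overrepresentation, primer dimers and off-target amplification. Three
#' abstractions are provided: `random_subset` draws `params$k` loci without
#' replacement (seeded); `drop_list` removes the named loci in
#' `params$drop`; `read_share` removes loci whose share of total reads in
#' `params$read_share` (named numeric, summing to <= 1) strictly exceeds
#' `params$max_share` (default 0.02).
#'
#' @param candidates candidate table (must contain `locus_id`).
#' @param mode one of `"random_subset"`, `"drop_list"`, `"read_share"`.
#' @param params mode parameters, see Description.
#' @param seed integer seed (used by `random_subset`).
#' @return the reduced candidate table, theta order preserved.
#' @export
model_primer_dropout <- function(candidates,
                                 mode = c("random_subset", "drop_list",
                                          "read_share"),
                                 params = list(), seed = 1L) {
  mode <- match.arg(mode)
  if (!nrow(candidates)) stop_param("candidates must be nonempty")
  ids <- candidates$locus_id
  keep_ids <- switch(mode,
    random_subset = {
      k <- params$k
      if (is.null(k) || k > length(ids)) {
        stop_param("random_subset needs params$k <= panel size")
      }
      set.seed(seed)
      sort(sample(ids, k))
    },
    drop_list = {
      drop <- params$drop %||% character(0)
      unknown <- setdiff(drop, ids)
      if (length(unknown)) {
        stop_param("drop_list names unknown loci: ",
                   paste(head(unknown, 5), collapse = ", "))
      }
      setdiff(ids, drop)
    },
    read_share = {
      shares <- params$read_share
      if (is.null(names(shares))) stop_param("read_share must be named")
      max_share <- params$max_share %||% 0.02
      over <- names(shares)[shares > max_share]
      setdiff(ids, over)
    })
  candidates[candidates$locus_id %in% keep_ids, , drop = FALSE]
}

#' Run the full candidate-locus filter chain
#'
#' Computes per-locus statistics and applies, in order: quality filters
#' (call rate, MAF), homeolog screen, HWE filter, tag-position window and
#' theta ranking, and linkage pruning with truncation to the candidate
#' panel size.
#'
#' @param panel a `ref_panel`.
#' @param config a [filter_config()].
#' @param seed integer seed for the linkage permutation tests.
#' @param stats optional precomputed [locus_stats_table()] to avoid
#'   recomputation.
#' @return list with `candidates` (final ranked candidate table), `report`
#'   (stage-count table whose n_out of each stage equals n_in of the
#'   next), `reasons` (first removal reason per removed locus), and
#'   `stats` (the full statistics table).
#' @export
design_panel <- function(panel, config = filter_config(), seed = 1L,
                         stats = NULL) {
  stopifnot(inherits(panel, "ref_panel"))
  if (is.null(stats)) stats <- locus_stats_table(panel)

  q <- apply_quality_filters(stats, config)
  h <- homeolog_filter(q$kept, config)
  w <- hwe_filter(h$kept, config)
  pr <- position_and_rank(w$kept, config)
  ld <- ld_prune(pr$kept, panel$geno, config, seed = seed, pop = panel$pop)

  report <- rbind(q$report, h$report, w$report, pr$report, ld$report)
  reasons <- c(q$reasons, h$reasons, w$reasons, pr$reasons, ld$reasons)
  list(candidates = ld$kept, report = report, reasons = reasons,
       stats = stats)
}
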