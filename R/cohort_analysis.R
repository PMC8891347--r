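#' Filter individuals by missing-data fraction
#'
#' Removes individuals whose fraction of missing genotype calls is
#' strictly greater than `max_missing` (default 0.25, i.e. an individual
#' at exactly 25% missing is kept).
#'
#' @param geno individuals x loci genotype matrix.
#' @param max_missing maximum tolerated missing fraction.
#' @return list with `geno` (kept rows), `kept` (logical vector over input
#'   rows), and `missing_fraction` (per input individual).
#' @export
filter_individuals_by_missingness <- function(geno, max_missing = 0.25) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  miss <- rowMeans(is.na(geno))
  kept <- miss <= max_missing
  list(geno = geno[kept, , drop = FALSE], kept = kept,
       missing_fraction = miss)
}

#' Hybrid summary of one year's class counts
#'
#' @param counts named counts over (a subset of) the six classes.
#' @return list with `n`, `proportions` (full six-class vector),
#'   `hybrid_fraction` (F1 + F2 + BC0 + BC1 over n), and
#'   `advanced_fraction` (F2 + BC0 + BC1 over all hybrids; `NA` when there
#'   are no hybrids).
#' @export
hybrid_summary <- function(counts) {
  if (is.null(names(counts)) || !all(names(counts) %in% HYBRID_CLASSES)) {
    stop_param("counts must be named with classes among: ",
               paste(HYBRID_CLASSES, collapse = ", "))
  }
  full <- setNames(rep(0, 6), HYBRID_CLASSES)
  full[names(counts)] <- counts
  n <- sum(full)
  if (n < 1) stop_param("counts must sum to at least 1")
  hybrids <- sum(full[HYBRID_ONLY_CLASSES])
  advanced <- sum(full[c("F2", "BC0", "BC1")])
  list(n = n,
       proportions = full / n,
       hybrid_fraction = hybrids / n,
       advanced_fraction = if (hybrids > 0) advanced / hybrids else NA_real_)
}

#' Stock composition by sample year
#'
#' Tabulates max-posterior class assignments by year into per-year counts
#' and proportions with a hybrid summary, mirroring the layout of a
#' stock-composition table of spawners.
#'
#' @param classes character vector of assigned classes (one per
#'   individual), or the assignment data frame from [assign_plugin()].
#' @param years vector of sample years, same length.
#' @return object of class `cohort_table`: list with `counts` (years x
#'   classes integer matrix), `proportions` (row-normalized), `n` (per
#'   year), `hybrid_fraction` and `advanced_fraction` (per year).
#' @export
stock_composition <- function(classes, years) {
  if (is.data.frame(classes)) classes <- classes$max_class
  if (length(classes) != length(years)) {
    stop_param("classes and years must have equal length")
  }
  bad <- setdiff(unique(classes), HYBRID_CLASSES)
  if (length(bad)) stop_param("unknown class label: ", bad[1])
  cls <- factor(classes, levels = HYBRID_CLASSES)
  counts <- unclass(table(year = years, class = cls))
  n <- rowSums(counts)
  props <- sweep(counts, 1, n, `/`)
  hs <- apply(counts, 1, function(x) hybrid_summary(setNames(x, HYBRID_CLASSES)))
  structure(list(
    counts = counts,
    proportions = props,
    n = n,
    hybrid_fraction = vapply(hs, `[[`, numeric(1), "hybrid_fraction"),
    advanced_fraction = vapply(hs, `[[`, numeric(1), "advanced_fraction")
  ), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Stock composition (counts):\n")
  print(x$counts)
  cat("\nProportions:\n")
  print(round(x$proportions, 2))
  cat("\nHybrid fraction:", sprintf("%.3f", x$hybrid_fraction), "\n")
  invisible(x)
}

#' Within-year test of equal class proportions
#'
#' Pearson goodness-of-fit of one year's six class counts against equal
#' proportions (df = 5), with an optional seeded Monte-Carlo exact
#' p-value.
#'
#' @param counts six class counts (any order; names optional).
#' @param simulate_p also compute a Monte-Carlo p-value.
#' @param n_sim Monte-Carlo replicates.
#' @param seed integer seed for the Monte-Carlo p-value.
#' @return list with `chi2`, `df`, `p`, and `p_exact` (`NA` unless
#'   `simulate_p`).
#' @export
within_year_class_test <- function(counts, simulate_p = FALSE,
                                   n_sim = 10000L, seed = 1L) {
  if (length(counts) != 6) stop_param("need counts for all six classes")
  if (sum(counts) < 1) stop_param("counts must sum to at least 1")
  ht <- suppressWarnings(chisq.test(counts, p = rep(1 / 6, 6)))
  p_exact <- NA_real_
  if (simulate_p) {
    set.seed(seed)
    hs <- suppressWarnings(chisq.test(counts, p = rep(1 / 6, 6),
                                      simulate.p.value = TRUE, B = n_sim))
    p_exact <- hs$p.value
  }
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, p_exact = p_exact)
}

#' Across-year test of one class's proportion
#'
#' Chi-square test of homogeneity of one class's proportion across years,
#' on the years x (class, not-class) contingency table (df = years - 1),
#' with an optional seeded Monte-Carlo exact p-value (Fisher-style).
#'
#' @param class_counts per-year counts of the class.
#' @param totals per-year total sample sizes.
#' @param simulate_p,n_sim,seed as [within_year_class_test()].
#' @return list with `chi2`, `df`, `p`, `p_exact`.
#' @export
across_year_class_test <- function(class_counts, totals, simulate_p = FALSE,
                                   n_sim = 10000L, seed = 1L) {
  if (length(class_counts) < 2) stop_param("need at least two years")
  if (length(class_counts) != length(totals)) {
    stop_param("class_counts and totals must have equal length")
  }
  if (any(totals < 1)) stop_param("every year needs a nonzero total")
  if (any(class_counts > totals)) stop_param("class_counts cannot exceed totals")
  tab <- rbind(in_class = class_counts, not_class = totals - class_counts)
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  p_exact <- NA_real_
  if (simulate_p) {
    set.seed(seed)
    hs <- suppressWarnings(chisq.test(tab, simulate.p.value = TRUE, B = n_sim))
    p_exact <- hs$p.value
  }
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, p_exact = p_exact)
}

#' Fork-length comparison across assigned classes
#'
#' One-way ANOVA of fork length on assigned class with post-hoc Tukey HSD
#' pairwise comparisons — the standard morphometric check that pure
#' anadromous fish are larger than residents, with hybrids in between.
#'
#' @param lengths numeric fork lengths.
#' @param classes class labels, same length; groups with fewer than 2
#'   observations are dropped with a message.
#' @return list with `anova_F`, `df`, `p`, `tukey` (data frame of pairwise
#'   comparisons: `comparison`, `diff`, `lwr`, `upr`, `p_adj`), and the
#'   fitted `model`.
#' @export
fork_length_comparison <- function(lengths, classes) {
  stopifnot(length(lengths) == length(classes))
  keep <- !is.na(lengths) & !is.na(classes)
  lengths <- lengths[keep]
  classes <- as.character(classes[keep])
  sizes <- table(classes)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    message("dropping groups with < 2 observations: ",
            paste(small, collapse = ", "))
    keep2 <- !classes %in% small
    lengths <- lengths[keep2]
    classes <- classes[keep2]
  }
  if (length(unique(classes)) < 2) {
    stop_param("need at least two groups with >= 2 observations")
  }
  d <- data.frame(length = lengths, class = factor(classes))
  fit <- aov(length ~ class, data = d)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$class
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(anova_F = an[["F value"]][1],
       df = as.numeric(c(an[["Df"]][1], an[["Df"]][2])),
       p = an[["Pr(>F)"]][1],
       tukey = tukey,
       model = fit)
}
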