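#' Row-normalized confusion matrix of class assignment
#'
#' Rows are true classes, columns assigned classes (max-posterior, no
#' threshold); each row gives the proportions of that true class assigned
#' to each class and sums to 1.
#'
#' @param true_labels character vector of true classes.
#' @param assigned character vector of assigned classes (e.g. the
#'   `max_class` column of an assignment result), same length.
#' @return 6 x 6 numeric matrix with dimnames in canonical class order.
#' @export
confusion_matrix <- function(true_labels, assigned) {
  if (length(true_labels) != length(assigned)) {
    stop_param("label vectors must have equal length")
  }
  bad <- setdiff(unique(c(true_labels, assigned)), HYBRID_CLASSES)
  if (length(bad)) stop_param("unknown class label: ", bad[1])
  tt <- factor(true_labels, levels = HYBRID_CLASSES)
  aa <- factor(assigned, levels = HYBRID_CLASSES)
  counts <- table(true = tt, assigned = aa)
  prop <- sweep(unclass(counts), 1, pmax(rowSums(counts), 1), `/`)
  prop
}

#' Accuracy, efficiency and power across posterior thresholds
#'
#' At threshold `t` an individual is assigned iff its maximum posterior is
#' `>= t`; below it the individual is unassigned. Per class `c` and
#' threshold:
#' accuracy = correct assignments to `c` / all assignments to `c`;
#' efficiency = correct assignments to `c` / number of true-`c`
#' individuals; power = accuracy x efficiency. Accuracy is `NA` (not zero)
#' for classes that receive no assignments at a threshold.
#'
#' @param assignments assignment data frame from [assign_plugin()] /
#'   [assign_gibbs()] (needs `max_class` and `max_posterior`).
#' @param true_labels character vector of true classes.
#' @param thresholds numeric grid in `[0, 1)`; default `0.50, 0.55, ...,
#'   0.95`.
#' @return data frame: `class`, `threshold`, `n_true`, `n_assigned`,
#'   `n_correct`, `accuracy`, `efficiency`, `power`.
#' @export
power_curves <- function(assignments, true_labels,
                         thresholds = seq(0.50, 0.95, by = 0.05)) {
  if (!length(thresholds)) stop_param("threshold grid must be nonempty")
  if (any(thresholds < 0 | thresholds >= 1)) {
    stop_param("thresholds must be in [0, 1)")
  }
  stopifnot(nrow(assignments) == length(true_labels))
  out <- list()
  for (t in thresholds) {
    ok <- assignments$max_posterior >= t
    for (cl in HYBRID_CLASSES) {
      n_true <- sum(true_labels == cl)
      assigned_c <- ok & assignments$max_class == cl
      n_assigned <- sum(assigned_c)
      n_correct <- sum(assigned_c & true_labels == cl)
      accuracy <- if (n_assigned > 0) n_correct / n_assigned else NA_real_
      efficiency <- if (n_true > 0) n_correct / n_true else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        class = cl, threshold = t, n_true = n_true,
        n_assigned = n_assigned, n_correct = n_correct,
        accuracy = accuracy, efficiency = efficiency,
        power = accuracy * efficiency, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Type I and Type II error rates of hybrid detection
#'
#' Type I (false positive): known pure individuals max-assigned to any
#' hybrid class, over the total number of pure individuals. Type II (false
#' negative): known hybrids max-assigned to a pure class, over the total
#' number of hybrids.
#'
#' @inheritParams power_curves
#' @return list with `type_I` and `type_II` fractions.
#' @export
error_rates <- function(assignments, true_labels) {
  stopifnot(nrow(assignments) == length(true_labels))
  is_pure_true <- true_labels %in% PURE_CLASSES
  if (!any(is_pure_true) || all(is_pure_true)) {
    stop_param("need at least one pure and one hybrid individual")
  }
  assigned_hybrid <- assignments$max_class %in% HYBRID_ONLY_CLASSES
  list(
    type_I = sum(is_pure_true & assigned_hybrid) / sum(is_pure_true),
    type_II = sum(!is_pure_true & !assigned_hybrid) / sum(!is_pure_true)
  )
}

#' Full evaluation report for one simulated cohort
#'
#' Convenience wrapper producing the confusion matrix, power curves and
#' error rates in one object.
#'
#' @inheritParams power_curves
#' @return list of class `evaluation_report` with elements `confusion`,
#'   `curves`, `type_I`, `type_II`.
#' @export
evaluate_assignments <- function(assignments, true_labels,
                                 thresholds = seq(0.50, 0.95, by = 0.05)) {
  er <- error_rates(assignments, true_labels)
  structure(list(
    confusion = confusion_matrix(true_labels, assignments$max_class),
    curves = power_curves(assignments, true_labels, thresholds),
    type_I = er$type_I,
    type_II = er$type_II
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Confusion matrix (rows = true class):\n")
  print(round(x$confusion, 3))
  cat(sprintf("\nType I error: %.4g  Type II error: %.4g\n",
              x$type_I, x$type_II))
  p50 <- x$curves[x$curves$threshold == 0.5, c("class", "power")]
  if (nrow(p50)) {
    cat("Power at threshold 0.5:\n")
    print(p50, row.names = FALSE)
  }
  invisible(x)
}
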