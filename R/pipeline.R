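#' Build a pipeline run configuration
#'
#' Collects everything one end-to-end run needs: the synthetic-data model
#' (or input paths), the filter configuration, simulation sizes, the
#' assignment mode with its MCMC parameters, and a single global seed from
#' which every stochastic stage derives its own seed. The configuration
#' round-trips losslessly through YAML via [read_run_config()] /
#' [write_run_config()].
#'
#' @param seed global integer seed.
#' @param model a [population_model()] for the synthetic reference data.
#' @param filter a [filter_config()].
#' @param panel_size final panel size drawn from the candidates by theta
#'   rank (the post-dropout panel).
#' @param n_per_class_design individuals per class in the design-stage
#'   informativeness simulation.
#' @param n_per_class_eval individuals per class in the evaluation
#'   simulation.
#' @param assign_mode `"plugin"` or `"gibbs"`.
#' @param n_burnin,n_sweeps MCMC parameters for `"gibbs"` mode.
#' @param out_dir optional directory; when set, every stage writes its TSV
#'   artifact there.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       model = population_model(seed = seed),
                       filter = filter_config(),
                       panel_size = 342L,
                       n_per_class_design = 1000L,
                       n_per_class_eval = 100L,
                       assign_mode = c("plugin", "gibbs"),
                       n_burnin = 10000L,
                       n_sweeps = 50000L,
                       out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), model = model, filter = filter,
              panel_size = as.integer(panel_size),
              n_per_class_design = as.integer(n_per_class_design),
              n_per_class_eval = as.integer(n_per_class_eval),
              assign_mode = match.arg(assign_mode),
              n_burnin = as.integer(n_burnin),
              n_sweeps = as.integer(n_sweeps),
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

# stage seeds derived deterministically from the global seed; offsets keep
# them distinct and inside the 32-bit integer range
stage_seed <- function(seed, stage) {
  (seed * 101L + stage * 7919L) %% .Machine$integer.max
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- unclass(config)
  plain$model <- unclass(plain$model)
  plain$filter <- unclass(plain$filter)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  model <- do.call(population_model, y$model)
  filt <- do.call(filter_config, y$filter)
  run_config(seed = y$seed, model = model, filter = filt,
             panel_size = y$panel_size,
             n_per_class_design = y$n_per_class_design,
             n_per_class_eval = y$n_per_class_eval,
             assign_mode = y$assign_mode,
             n_burnin = y$n_burnin, n_sweeps = y$n_sweeps,
             out_dir = y$out_dir)
}

#' Run the whole panel workflow end to end
#'
#' Executes design -> simulate -> assign -> evaluate -> cohort on
#' synthetic reference data: generates the two-population reference panel,
#' runs the candidate filter chain, selects the final panel of
#' `panel_size` loci by theta rank, estimates smoothed reference
#' frequencies, simulates evaluation cohorts of all six classes, assigns
#' them (plug-in or Gibbs), and produces the evaluation report and a
#' stock-composition table. Every stochastic stage receives a seed derived
#' from the global seed, so reruns with the same configuration are
#' identical; when `out_dir` is set, stage artifacts are written as TSV
#' stamped with the seed and a configuration hash.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with elements `ref_panel`,
#'   `design` (filter chain output), `panel` (final locus table),
#'   `ref_freqs`, `design_eval` and `eval` (evaluation reports at the
#'   design and evaluation cohort sizes), `assignments`, `truth`,
#'   `composition`, `config`, and `stage_log` (per-stage counts).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  note("stage 1/5: simulating reference panel (", config$model$n_loci,
       " loci)")
  ref <- simulate_rad_dataset(config$model)

  note("stage 2/5: filter chain")
  des <- design_panel(ref, config$filter, seed = stage_seed(config$seed, 2L))
  note("  candidates: ", nrow(des$candidates))

  n_panel <- min(config$panel_size, nrow(des$candidates))
  panel <- des$candidates[seq_len(n_panel), , drop = FALSE]
  note("  final panel: ", nrow(panel), " loci")

  panel_ref <- subset_ref_panel(ref, panel$locus_id)
  freqs <- estimate_reference_frequencies(panel_ref)

  note("stage 3/5: simulating evaluation cohorts")
  counts_design <- setNames(rep(config$n_per_class_design, 6), HYBRID_CLASSES)
  sim_design <- simulate_cohort(freqs$p0, freqs$p1, counts_design,
                                seed = stage_seed(config$seed, 3L))
  counts_eval <- setNames(rep(config$n_per_class_eval, 6), HYBRID_CLASSES)
  sim_eval <- simulate_cohort(freqs$p0, freqs$p1, counts_eval,
                              seed = stage_seed(config$seed, 4L))

  note("stage 4/5: assignment (", config$assign_mode, ")")
  assign_fun <- function(g) {
    if (config$assign_mode == "plugin") {
      assign_plugin(g, freqs)
    } else {
      assign_gibbs(g, panel_ref, n_burnin = config$n_burnin,
                   n_sweeps = config$n_sweeps,
                   seed = stage_seed(config$seed, 5L))
    }
  }
  asg_design <- assign_fun(sim_design$geno)
  asg_eval <- assign_fun(sim_eval$geno)

  note("stage 5/5: evaluation and composition")
  eval_design <- evaluate_assignments(asg_design, sim_design$labels)
  eval_eval <- evaluate_assignments(asg_eval, sim_eval$labels)
  comp <- stock_composition(asg_eval, rep("simulated", nrow(asg_eval)))

  result <- structure(list(
    ref_panel = ref, design = des, panel = panel, ref_freqs = freqs,
    design_eval = eval_design, eval = eval_eval,
    assignments = asg_eval, truth = sim_eval$labels,
    composition = comp, config = config, stage_log = log_lines
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- sprintf("# seed=%d config_hash=%s", config$seed,
                     config_hash(config))
    wr <- function(df, name) {
      p <- file.path(config$out_dir, name)
      con <- file(p, "w")
      writeLines(stamp, con)
      write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
    }
    wr(des$report, "filter_report.tsv")
    wr(panel, "panel.tsv")
    wr(asg_eval, "posteriors.tsv")
    wr(as.data.frame(eval_eval$curves), "power_curves.tsv")
    wr(as.data.frame(unclass(comp$counts)), "composition.tsv")
  }
  result
}

# short deterministic hash of the scientific configuration (output paths
# excluded; no digest dependency)
config_hash <- function(config) {
  plain <- unclass(config)
  plain$out_dir <- NULL
  s <- paste(deparse(plain), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("hybridpanel pipeline result\n")
  cat("  panel size:", nrow(x$panel), "loci\n")
  cat("  min confusion diagonal (design n):",
      sprintf("%.3f", min(diag(x$design_eval$confusion))), "\n")
  p50 <- x$eval$curves[x$eval$curves$threshold == 0.5, "power"]
  cat("  min power at 0.5 (eval n):", sprintf("%.3f", min(p50)), "\n")
  invisible(x)
}
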