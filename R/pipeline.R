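#' Validate and complete a run configuration
#'
#' Applies the package defaults (alpha = 0.4/0.4/0.2, t_max = 100,
#' rho = 0.9, 8 tasks, L = 10, gamma1 = 0.5, gamma2 = 1, 5 folds), checks
#' every downstream invariant up front and rejects unknown keys.
#'
#' @param raw named list of settings (e.g. parsed from a YAML/flat config
#'   file); an empty list yields the full defaults.
#' @return validated configuration list of class `run_config`.
#' @export
validate_config <- function(raw = list()) {
  defaults <- list(
    alphas = c(0.4, 0.4, 0.2), n_bins = 10, n_tasks = 8,
    task_mode = "per_task_lambda",
    pack_size = 30, t_max = 100, rho = 0.9, inner_cv_folds = 3,
    transfer_floor = 0.05, knowledge_transfer = TRUE, aggregate = "majority",
    penalty_scope = "task", C = 1,
    folds = 5, positive = 0,
    L = 10, gamma1 = 0.5, gamma2 = 1, target_label = 1,
    learning_rate = 0.05, max_iters = 1000, init_noise_sd = 0.1,
    diag_jitter_scale = 1e-4,
    synthetic = list(), seed = 1, out_dir = NULL, explain_subject = NULL)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  if (abs(sum(cfg$alphas) - 1) > 1e-12)
    stopf("alphas must sum to 1 (got %g)", sum(cfg$alphas))
  if (cfg$n_tasks < 1) stopf("n_tasks must be at least 1")
  if (cfg$rho < 0 || cfg$rho > 1) stopf("rho must lie in [0, 1]")
  if (cfg$folds < 2) stopf("folds must be at least 2")
  # these constructors enforce the remaining invariants
  gwo_control(pack_size = cfg$pack_size, t_max = cfg$t_max, rho = cfg$rho,
              inner_cv_folds = cfg$inner_cv_folds,
              transfer_floor = cfg$transfer_floor,
              knowledge_transfer = cfg$knowledge_transfer,
              aggregate = cfg$aggregate, penalty_scope = cfg$penalty_scope,
              C = cfg$C)
  cf_control(L = cfg$L, gamma1 = cfg$gamma1, gamma2 = cfg$gamma2,
             target_label = cfg$target_label, learning_rate = cfg$learning_rate,
             max_iters = cfg$max_iters, init_noise_sd = cfg$init_noise_sd,
             diag_jitter_scale = cfg$diag_jitter_scale)
  structure(cfg, class = "run_config")
}

#' Run the full pipeline end to end
#'
#' simulate (or load) -> weights -> tasks -> select -> train -> evaluate ->
#' explain, writing each stage's tabular output under `out_dir` together
#' with a JSON manifest of the configuration, per-stage seeds, timings and
#' output-file digests.  Per-stage seeds are derived deterministically
#' from the master seed, so identical configurations reproduce identical
#' outputs byte for byte.
#'
#' @param config a [validate_config()] result or raw named list.
#' @param ds optional [feature_dataset()]; when NULL a synthetic dataset is
#'   generated from `config$synthetic` (see [synthetic_spec()]).
#' @param out_dir output directory; overrides `config$out_dir`.
#' @param stages subset of c("weights", "select", "evaluate", "explain") to
#'   run (earlier stages a later one needs are always run).
#' @param quiet suppress progress messages.
#' @return the run manifest, invisibly, with the fitted objects attached as
#'   attributes `fit`, `cv`, `cfs`.
#' @export
run_end_to_end <- function(config = list(), ds = NULL, out_dir = NULL,
                           stages = c("weights", "select", "evaluate", "explain"),
                           quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% stopf("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- match.arg(stages, several.ok = TRUE)
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  timings <- list(); seeds <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  if (is.null(ds)) {
    seeds$simulate <- derive_seed(cfg$seed, "simulate")
    say("simulate: synthetic dataset")
    syn <- tick("simulate", synthesize_dataset(
      do.call(synthetic_spec, utils::modifyList(cfg$synthetic,
                                                list(seed = seeds$simulate)))))
    ds <- syn$dataset
    utils::write.table(data.frame(planted_edge = syn$planted),
                       file.path(out_dir, "planted.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  ctrl <- gwo_control(pack_size = cfg$pack_size, t_max = cfg$t_max, rho = cfg$rho,
                      inner_cv_folds = cfg$inner_cv_folds,
                      transfer_floor = cfg$transfer_floor,
                      knowledge_transfer = cfg$knowledge_transfer,
                      aggregate = cfg$aggregate, penalty_scope = cfg$penalty_scope,
                      C = cfg$C)

  fit <- NULL; cv <- NULL; cfs <- NULL
  need_fit <- any(c("select", "explain") %in% stages)
  if ("weights" %in% stages && !need_fit) {
    say("weights: filter scores only")
    w <- tick("weights", feature_weights(ds, alphas = cfg$alphas, n_bins = cfg$n_bins))
    utils::write.table(weight_report(ds, w), file.path(out_dir, "weights.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (need_fit) {
    say("weights + tasks + select: fitting the model")
    seeds$fit <- derive_seed(cfg$seed, "fit")
    fit <- tick("select", fcselect(ds, alphas = cfg$alphas, n_tasks = cfg$n_tasks,
                                   n_bins = cfg$n_bins, task_mode = cfg$task_mode,
                                   control = ctrl, seed = seeds$fit))
    utils::write.table(weight_report(ds, fit$weights),
                       file.path(out_dir, "weights.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    {
      sel <- data.frame(feature_id = seq_len(ncol(ds$features)),
                        roi_a = ds$edge_index$name_a, roi_b = ds$edge_index$name_b,
                        selected = as.integer(fit$multitask$aggregated_mask),
                        frequency = fit$multitask$selection_frequency,
                        tasks_selected = fit$multitask$kb_counts)
      utils::write.table(sel, file.path(out_dir, "selection.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      trace <- do.call(rbind, lapply(fit$multitask$task_results, function(r)
        data.frame(task_id = r$task_id,
                   iteration = seq_along(r$fitness_trace) - 1L,
                   best_fitness = r$fitness_trace)))
      utils::write.table(trace, file.path(out_dir, "trace.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  if ("evaluate" %in% stages) {
    say("evaluate: nested %d-fold cross-validation", cfg$folds)
    seeds$evaluate <- derive_seed(cfg$seed, "evaluate")
    cv <- tick("evaluate", cross_validate_pipeline(
      ds, folds = cfg$folds, seed = seeds$evaluate, alphas = cfg$alphas,
      n_tasks = cfg$n_tasks, n_bins = cfg$n_bins, control = ctrl,
      positive = cfg$positive))
    utils::write.table(round(cv$folds, 6), file.path(out_dir, "cv_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if ("explain" %in% stages) {
    subject <- cfg$explain_subject %||% which(ds$labels == 0)[1]
    say("explain: counterfactuals for subject %d", subject)
    seeds$explain <- derive_seed(cfg$seed, "explain")
    cfc <- cf_control(L = cfg$L, gamma1 = cfg$gamma1, gamma2 = cfg$gamma2,
                      target_label = cfg$target_label,
                      learning_rate = cfg$learning_rate, max_iters = cfg$max_iters,
                      init_noise_sd = cfg$init_noise_sd,
                      diag_jitter_scale = cfg$diag_jitter_scale,
                      seed = seeds$explain)
    cfs <- tick("explain", explain_subject(fit, subject, control = cfc))
    utils::write.table(change_report(cfs, ds$edge_index),
                       file.path(out_dir, "counterfactuals.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(validity_rate = mean(cfs$valid),
                              loss = cfs$loss[c("hinge", "proximity", "diversity", "total")],
                              iterations = cfs$iterations, subject = subject,
                              seed = seeds$explain),
                         file.path(out_dir, "cf_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  files <- list.files(out_dir, pattern = "\\.(tsv|json)$", full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(config = unclass(cfg)[setdiff(names(cfg), "out_dir")],
                   seeds = seeds, stages = stages, timings = timings,
                   package_version = as.character(utils::packageVersion("fcselect")),
                   digests = as.list(tools::md5sum(sort(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- manifest
  attr(out, "fit") <- fit; attr(out, "cv") <- cv; attr(out, "cfs") <- cfs
  invisible(out)
}
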