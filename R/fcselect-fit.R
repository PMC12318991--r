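#' Fit the multi-task Grey Wolf feature-selection classifier
#'
#' The package's central model fit.  Given a two-class edge-feature
#' dataset, it (i) weights every edge by a hybrid filter (Fisher criterion,
#' mutual information, dispersion), (ii) stratifies the ranked weight
#' curve at its knee points, (iii) generates `n_tasks` related candidate
#' sets by probabilistic extraction, (iv) solves each task with a binary
#' Grey Wolf Optimizer whose later tasks are initialized from the
#' selection history of earlier ones, (v) aggregates the per-task best
#' subsets into one feature subset, and (vi) trains a linear maximum-
#' margin classifier on it.
#'
#' @param ds a [feature_dataset()].
#' @param alphas filter combination weights (sum 1; default c(0.4, 0.4, 0.2)).
#' @param n_tasks number of selection tasks (default 8).
#' @param n_bins equal-frequency bins for the mutual-information score.
#' @param task_mode lambda-draw mode of [generate_tasks()].
#' @param control optimizer settings, a [gwo_control()].
#' @param seed master seed; per-stage streams are derived from it, so a
#'   fit is fully reproducible.
#' @return object of class `fcselect`: the weight table, knee partition,
#'   task collection, multi-task optimizer result, selected feature ids,
#'   fitted `margin_model`, and the call.
#' @examples
#' syn <- synthesize_dataset(synthetic_spec(seed = 42))
#' fit <- fcselect(syn$dataset, n_tasks = 3,
#'                 control = gwo_control(pack_size = 8, t_max = 5), seed = 1)
#' print(fit)
#' mean(predict(fit, syn$dataset) == syn$dataset$labels)
#' @export
fcselect <- function(ds, alphas = c(0.4, 0.4, 0.2), n_tasks = 8, n_bins = 10,
                     task_mode = "per_task_lambda", control = gwo_control(),
                     seed = NULL) {
  stopifnot(inherits(ds, "feature_dataset"))
  weights <- feature_weights(ds, alphas = alphas, n_bins = n_bins)
  knees <- detect_knees(weights$combined[weights$rank_order])
  probs <- selection_probabilities(weights)
  tasks <- generate_tasks(probs$P_adj, n = n_tasks,
                          seed = derive_seed(seed, "tasks"), mode = task_mode)
  ctrl <- control
  ctrl$seed <- derive_seed(seed, "gwo")
  mt <- run_multitask(tasks, ds, ctrl, p_adj = probs$P_adj)
  model <- train_margin_model(ds, mask = mt$aggregated_mask, C = control$C)
  structure(list(weights = weights, knees = knees, probabilities = probs,
                 tasks = tasks, multitask = mt,
                 selected = which(mt$aggregated_mask), model = model,
                 dataset = ds, seed = seed, call = match.call()),
            class = "fcselect")
}

#' @export
print.fcselect <- function(x, ...) {
  cat("Multi-task Grey Wolf feature selection fit\n")
  cat(sprintf("  %d subjects, %d edge features (%d ROIs)\n",
              nrow(x$dataset$features), ncol(x$dataset$features), x$dataset$n_rois))
  cat(sprintf("  %d tasks -> %d selected edges; best task fitness %.4f\n",
              nrow(x$tasks$masks), length(x$selected),
              max(vapply(x$multitask$task_results, `[[`, numeric(1), "best_fitness"))))
  invisible(x)
}

#' @param object,x an `fcselect` fit.
#' @param ... unused.
#' @rdname fcselect
#' @export
summary.fcselect <- function(object, ...) {
  tr <- object$multitask$task_results
  tab <- data.frame(task = vapply(tr, `[[`, integer(1), "task_id"),
                    candidates = rowSums(object$tasks$masks),
                    best_fitness = vapply(tr, `[[`, numeric(1), "best_fitness"),
                    subset_size = vapply(tr, function(r) sum(r$best_mask), integer(1)))
  sel <- object$dataset$edge_index[object$selected, c("edge_id", "name_a", "name_b")]
  sel$frequency <- object$multitask$selection_frequency[object$selected]
  out <- list(tasks = tab, selected_edges = sel, knees = object$knees,
              train_accuracy = mean(predict(object$model, object$dataset$features) ==
                                      object$dataset$labels))
  class(out) <- "summary.fcselect"
  out
}

#' @export
print.summary.fcselect <- function(x, ...) {
  cat("Per-task optimization:\n")
  print(x$tasks, row.names = FALSE)
  print(x$knees)
  cat(sprintf("Selected edges (%d), training accuracy %.4f:\n",
              nrow(x$selected_edges), x$train_accuracy))
  print(utils::head(x$selected_edges, 20), row.names = FALSE)
  invisible(x)
}

#' @rdname fcselect
#' @export
coef.fcselect <- function(object, ...) {
  stats::setNames(c(object$model$bias, object$model$weights),
                  c("(bias)", paste0("edge", object$selected)))
}

#' @param newdata a [feature_dataset()] or feature matrix in the full edge
#'   space.
#' @rdname fcselect
#' @export
predict.fcselect <- function(object, newdata = object$dataset, ...) {
  predict(object$model, newdata)
}

#' @param which "trace" plots per-task best-fitness traces; "weights" the
#'   ranked weight curve with knee points.
#' @rdname fcselect
#' @export
plot.fcselect <- function(x, which = c("trace", "weights"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    traces <- lapply(x$multitask$task_results, `[[`, "fitness_trace")
    ylim <- range(unlist(traces))
    plot(NULL, xlim = c(0, length(traces[[1]]) - 1), ylim = ylim,
         xlab = "iteration", ylab = "best fitness",
         main = "Per-task GWO fitness traces")
    for (i in seq_along(traces))
      graphics::lines(seq_along(traces[[i]]) - 1, traces[[i]], col = i)
    graphics::legend("bottomright", legend = paste("task", seq_along(traces)),
                     col = seq_along(traces), lty = 1, cex = 0.7)
  } else {
    w <- x$weights$combined[x$weights$rank_order]
    plot(w, type = "l", xlab = "rank", ylab = "combined weight",
         main = "Ranked feature weights")
    for (k in c(x$knees$knee1, x$knees$knee2))
      if (!is.na(k)) graphics::abline(v = k, lty = 2)
  }
  invisible(x)
}

#' Counterfactual explanations for subjects of a fitted model
#'
#' Convenience wrapper around [generate_counterfactuals()] for an
#' [fcselect()] fit: perturbs only the selected edges of the chosen
#' subject, holding all other edges at their observed values.
#'
#' @param fit an `fcselect` object.
#' @param subject row index of the subject to explain.
#' @param control a [cf_control()].
#' @return a `counterfactual_set` (see [generate_counterfactuals()]).
#' @export
explain_subject <- function(fit, subject, control = cf_control()) {
  stopifnot(inherits(fit, "fcselect"))
  x <- fit$dataset$features[subject, ]
  generate_counterfactuals(fit$model, x, fit$dataset, control = control)
}
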