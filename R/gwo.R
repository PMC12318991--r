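#' Optimizer settings for the multi-task Grey Wolf feature selector
#'
#' @param pack_size number of wolves (candidate subsets) per task; >= 4.
#' @param t_max iterations per task.
#' @param rho fitness weight in \[0, 1\] balancing inner-CV accuracy against
#'   subset size: fitness = rho * ACC - (1 - rho) * q_sf / q_task.
#' @param seed integer seed for the whole multi-task run.
#' @param inner_cv_folds stratified folds for the accuracy term (default 3).
#' @param transfer_floor minimum cross-task inclusion probability, so
#'   features with no selection history are never permanently extinct.
#' @param knowledge_transfer use cross-task selection counts to initialize
#'   later tasks (default TRUE; FALSE is the ablation condition).
#' @param aggregate how the n per-task best subsets become one:
#'   "majority" (selected by more than n/2 tasks, falling back to the
#'   best-fitness task's subset when empty), "best", or "union".
#' @param penalty_scope "task" normalizes the size penalty by the task's
#'   candidate count, "global" by the full feature count q.
#' @param C soft-margin cost of the inner classifier.
#' @return list of class `gwo_control`.
#' @export
gwo_control <- function(pack_size = 30, t_max = 100, rho = 0.9, seed = NULL,
                        inner_cv_folds = 3, transfer_floor = 0.05,
                        knowledge_transfer = TRUE,
                        aggregate = c("majority", "best", "union"),
                        penalty_scope = c("task", "global"), C = 1) {
  aggregate <- match.arg(aggregate)
  penalty_scope <- match.arg(penalty_scope)
  if (pack_size < 4) stopf("pack_size must be at least 4")
  if (t_max < 1) stopf("t_max must be at least 1")
  if (rho < 0 || rho > 1) stopf("rho must lie in [0, 1]")
  structure(list(pack_size = as.integer(pack_size), t_max = as.integer(t_max),
                 rho = rho, seed = seed, inner_cv_folds = as.integer(inner_cv_folds),
                 transfer_floor = transfer_floor,
                 knowledge_transfer = knowledge_transfer,
                 aggregate = aggregate, penalty_scope = penalty_scope, C = C),
            class = "gwo_control")
}

#' Grey Wolf coefficient vectors
#'
#' The convergence factor decays linearly from 2 to 0 over the run,
#' d = 2 (1 - t / t_max); per dimension A = 2 d r1 - d and C = 2 r2 with
#' r1, r2 ~ U(0, 1), so |A| <= d (exploration shrinks as t grows) and
#' C in \[0, 2\].  Draws come from the current RNG stream.
#'
#' @param t current iteration (0..t_max).
#' @param t_max total iterations.
#' @param dim number of dimensions.
#' @return list(d, A, C) with A and C of length `dim`.
#' @export
coefficient_vectors <- function(t, t_max, dim) {
  if (t < 0 || t > t_max) stopf("t must lie in [0, t_max]")
  d <- 2 * (1 - t / t_max)
  r1 <- stats::runif(dim); r2 <- stats::runif(dim)
  list(d = d, A = 2 * d * r1 - d, C = 2 * r2)
}

#' One encircling update of a wolf position
#'
#' Moves a continuous position in \[0, 1\]^dim toward the three best-so-far
#' solutions: per leader i, D_i = |C_i * X_i - X| and the new position is
#' the mean of X_i - A_i * D_i over the alpha, beta and delta leaders,
#' clipped back to \[0, 1\].
#'
#' @param position numeric vector in \[0, 1\].
#' @param leaders list of three binary leader vectors (alpha, beta, delta).
#' @param t,t_max iteration counters governing the decay of A.
#' @return updated position, clipped to \[0, 1\].
#' @export
encircle_update <- function(position, leaders, t, t_max) {
  dim <- length(position)
  acc <- numeric(dim)
  for (ld in leaders) {
    cf <- coefficient_vectors(t, t_max, dim)
    D <- abs(cf$C * ld - position)
    acc <- acc + (ld - cf$A * D)
  }
  pmin(pmax(acc / length(leaders), 0), 1)
}

#' Decode a continuous wolf position to a binary feature mask
#'
#' @param position numeric vector in \[0, 1\].
#' @return logical mask, TRUE where position >= 0.5.
#' @export
binarize <- function(position) position >= 0.5

#' Subset fitness: penalized inner-CV accuracy
#'
#' fitness = rho * ACC - (1 - rho) * q_sf / q_task, where ACC is the mean
#' accuracy of the linear margin classifier under stratified inner
#' cross-validation on the training data, q_sf the subset size and q_task
#' the candidate-set size.  An empty mask scores -1.
#'
#' @param mask logical mask over the candidate features (columns of
#'   `features`).
#' @param features,labels training data restricted to the task candidates.
#' @param fold precomputed inner fold assignment (same length as labels).
#' @param control a [gwo_control()].
#' @param q_penalty denominator of the size penalty.
#' @return scalar fitness.
#' @export
subset_fitness <- function(mask, features, labels, fold, control, q_penalty = ncol(features)) {
  if (!any(mask)) return(-1)
  accs <- vapply(unique(fold), function(f) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2)
      stopf("inner training split lost a class; use stratified folds")
    model <- train_margin_model(list(features = features[tr, , drop = FALSE],
                                     labels = labels[tr]),
                                mask = mask, C = control$C)
    mean(predict(model, features[!tr, , drop = FALSE]) == labels[!tr])
  }, numeric(1))
  control$rho * mean(accs) - (1 - control$rho) * (sum(mask) / q_penalty)
}

#' Cross-task transfer probabilities from a knowledge base
#'
#' Converts cumulative selection counts into inclusion probabilities
#' P(s_j) = Q_j / sum(Q), floored at `floor` so zero-history features keep
#' a small inclusion chance.  With no history at all, NULL is returned and
#' the caller falls back to the weight-based probabilities.
#'
#' @param counts integer vector of cross-task selection counts.
#' @param floor minimum probability (default 0.05).
#' @return probability vector, or NULL when all counts are zero.
#' @export
transfer_probabilities <- function(counts, floor = 0.05) {
  s <- sum(counts)
  if (s <= 0) return(NULL)
  pmax(counts / s, floor)
}

#' Initialize a wolf pack by Bernoulli sampling
#'
#' Each wolf dimension is set to 1 with probability `p_init` (independent
#' uniform draw <= p_init), stored as 0/1 continuous positions.
#'
#' @param p_init per-dimension inclusion probabilities.
#' @param pack_size number of wolves.
#' @return pack_size x dim numeric matrix of 0/1 positions.
#' @export
initialize_pack <- function(p_init, pack_size) {
  dim <- length(p_init)
  u <- matrix(stats::runif(pack_size * dim), pack_size, dim)
  (u <= matrix(p_init, pack_size, dim, byrow = TRUE)) * 1.0
}

# top-3 distinct-position leaders by fitness; ties broken by index
pick_leaders <- function(masks, fits) {
  ord <- order(-fits, seq_along(fits))
  idx <- ord[seq_len(min(3, length(ord)))]
  while (length(idx) < 3) idx <- c(idx, idx[length(idx)])
  list(masks = lapply(idx, function(i) masks[i, ] * 1.0), fits = fits[idx])
}

#' Run the Grey Wolf optimizer on one feature-selection task
#'
#' Initializes the pack from transfer probabilities (or the weight-based
#' probabilities when no history exists), then iterates: every wolf takes
#' an encircling step toward the three best-so-far binary solutions, is
#' decoded by [binarize()], and evaluated by [subset_fitness()] (memoized
#' by mask).  Leaders are elitist, so the best-so-far trace never
#' decreases.
#'
#' @param task_mask logical length-q candidate mask of this task.
#' @param ds training [feature_dataset()].
#' @param control a [gwo_control()].
#' @param p_init length-q initialization probabilities (already restricted
#'   probabilities are taken via `task_mask`).
#' @param task_id identifier recorded in the result.
#' @param seed integer seed for this task's RNG stream.
#' @return object of class `task_result`: `best_mask` (length-q logical in
#'   the global feature space), `best_fitness`, `fitness_trace`
#'   (length t_max + 1, position 1 = after initialization),
#'   `init_best_fitness`, `task_id`, `n_evals`.
#' @export
run_gwo_task <- function(task_mask, ds, control, p_init, task_id = 1L, seed = NULL) {
  dims <- which(task_mask)
  if (length(dims) == 0) stopf("task candidate set is empty")
  q_task <- length(dims)
  x <- ds$features[, dims, drop = FALSE]
  y <- ds$labels
  q_pen <- if (control$penalty_scope == "task") q_task else ncol(ds$features)

  with_seed(seed, {
    fold <- stratified_folds(y, control$inner_cv_folds)
    cache <- new.env(parent = emptyenv())
    n_evals <- 0L
    fit_of <- function(mask) {
      key <- paste(which(mask), collapse = ",")
      if (key == "") key <- "-"
      got <- cache[[key]]
      if (!is.null(got)) return(got)
      n_evals <<- n_evals + 1L
      val <- subset_fitness(mask, x, y, fold, control, q_penalty = q_pen)
      cache[[key]] <- val
      val
    }

    pack <- initialize_pack(p_init[dims], control$pack_size)
    masks <- pack >= 0.5
    fits <- apply(masks, 1, fit_of)
    leaders <- pick_leaders(masks, fits)
    best_mask <- leaders$masks[[1]] >= 0.5
    best_fit <- leaders$fits[1]
    trace <- numeric(control$t_max + 1)
    trace[1] <- best_fit
    init_best <- best_fit

    for (t in seq_len(control$t_max)) {
      for (i in seq_len(control$pack_size)) {
        pack[i, ] <- encircle_update(pack[i, ], leaders$masks, t, control$t_max)
      }
      masks <- pack >= 0.5
      fits <- apply(masks, 1, fit_of)
      # elitist leader refresh: keep previous leaders in the pool
      pool_masks <- rbind(masks, do.call(rbind, leaders$masks) >= 0.5)
      pool_fits <- c(fits, leaders$fits)
      leaders <- pick_leaders(pool_masks, pool_fits)
      if (leaders$fits[1] > best_fit) {
        best_fit <- leaders$fits[1]
        best_mask <- leaders$masks[[1]] >= 0.5
      }
      trace[t + 1] <- best_fit
    }

    global_mask <- rep(FALSE, ncol(ds$features))
    global_mask[dims[best_mask]] <- TRUE
    structure(list(best_mask = global_mask, best_fitness = best_fit,
                   fitness_trace = trace, init_best_fitness = init_best,
                   task_id = task_id, n_evals = n_evals),
              class = "task_result")
  })
}

#' Multi-task Grey Wolf feature selection with knowledge transfer
#'
#' Processes the tasks sequentially.  Each task's pack is initialized from
#' the cross-task knowledge base (cumulative selection counts of previous
#' task solutions, Bernoulli probabilities floored at `transfer_floor`);
#' the first task — or every task when `knowledge_transfer = FALSE` —
#' falls back to the weight-based probabilities `p_adj`.  After each task
#' the knowledge base is incremented by the task's best mask.  The n task
#' bests are aggregated into one subset by the rule in [gwo_control()].
#'
#' @param tasks a `task_collection` from [generate_tasks()].
#' @param ds training [feature_dataset()].
#' @param control a [gwo_control()].
#' @param p_adj length-q weight-based selection probabilities (fallback
#'   initialization).
#' @return object of class `multitask_result`: `task_results`,
#'   `aggregated_mask` (length-q logical), `selection_frequency`
#'   (fraction of task bests selecting each feature), `kb_counts`.
#' @export
run_multitask <- function(tasks, ds, control = gwo_control(), p_adj) {
  stopifnot(inherits(tasks, "task_collection"))
  n <- nrow(tasks$masks)
  q <- ncol(tasks$masks)
  if (ncol(ds$features) != q) stopf("task masks and dataset disagree on q")
  kb <- integer(q)
  results <- vector("list", n)
  for (i in seq_len(n)) {
    p_init <- NULL
    if (control$knowledge_transfer)
      p_init <- transfer_probabilities(kb, floor = control$transfer_floor)
    if (is.null(p_init)) p_init <- p_adj
    results[[i]] <- run_gwo_task(tasks$masks[i, ], ds, control, p_init,
                                 task_id = i,
                                 seed = derive_seed(control$seed, paste0("task", i)))
    kb <- kb + as.integer(results[[i]]$best_mask)
  }
  best_masks <- do.call(rbind, lapply(results, `[[`, "best_mask"))
  freq <- colMeans(best_masks)
  agg <- switch(control$aggregate,
    majority = {
      m <- colSums(best_masks) > n / 2
      if (!any(m)) {
        bi <- which.max(vapply(results, `[[`, numeric(1), "best_fitness"))
        m <- results[[bi]]$best_mask
      }
      m
    },
    best = {
      bi <- which.max(vapply(results, `[[`, numeric(1), "best_fitness"))
      results[[bi]]$best_mask
    },
    union = colSums(best_masks) > 0)
  structure(list(task_results = results, aggregated_mask = agg,
                 selection_frequency = freq, kb_counts = kb,
                 control = control),
            class = "multitask_result")
}

#' @export
print.multitask_result <- function(x, ...) {
  fits <- vapply(x$task_results, `[[`, numeric(1), "best_fitness")
  cat(sprintf("Multi-task GWO: %d tasks, best fitness %.4f, aggregated subset size %d\n",
              length(fits), max(fits), sum(x$aggregated_mask)))
  invisible(x)
}
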