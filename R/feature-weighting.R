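#' Fisher criterion scores
#'
#' Univariate class-separability score per edge feature:
#' \deqn{h_j = |\mu_{j,0} - \mu_{j,1}|^2 / (\sigma_{j,0}^2 + \sigma_{j,1}^2 + \epsilon)}
#' with population (divide-by-count) variances per class and a 1e-12 guard
#' against zero within-class variance.
#'
#' @param ds a [feature_dataset()], or a list with `features` and `labels`.
#' @return numeric vector of length q.
#' @export
fisher_scores <- function(ds) {
  x <- ds$features; y <- ds$labels
  if (length(unique(y)) < 2) stopf("both classes must be present")
  x0 <- x[y == 0, , drop = FALSE]; x1 <- x[y == 1, , drop = FALSE]
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  v0 <- pop_sd(x0)^2; v1 <- pop_sd(x1)^2
  (mu0 - mu1)^2 / (v0 + v1 + 1e-12)
}

#' Mutual information between each feature and the class label
#'
#' Each feature is discretized into `n_bins` equal-frequency bins (quantile
#' cut points; ties can merge bins) and the discrete mutual information
#' with the label is computed in nats, with the 0 log 0 = 0 convention.
#'
#' @param ds a [feature_dataset()].
#' @param n_bins number of equal-frequency bins (default 10).
#' @param normalize divide by the label entropy H(Y) (off by default; the
#'   raw double-sum definition is the package default).
#' @return numeric vector of length q (nats, or dimensionless if normalized).
#' @export
mutual_information_scores <- function(ds, n_bins = 10, normalize = FALSE) {
  if (n_bins < 2) stopf("n_bins must be at least 2")
  x <- ds$features; y <- ds$labels
  p <- nrow(x)
  hy <- discrete_entropy(tabulate(y + 1L, 2L) / p)
  out <- apply(x, 2, function(col) {
    br <- unique(stats::quantile(col, probs = seq(0, 1, length.out = n_bins + 1),
                                 names = FALSE, type = 7))
    if (length(br) < 2) return(0)
    z <- cut(col, breaks = br, include.lowest = TRUE, labels = FALSE)
    discrete_mi(table(z, y) / p)
  })
  if (normalize && hy > 0) out <- out / hy
  unname(out)
}

# MI of a joint probability table, nats, 0 log 0 = 0
discrete_mi <- function(joint) {
  pz <- rowSums(joint); py <- colSums(joint)
  ex <- outer(pz, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / ex[nz]))
}

discrete_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-feature dispersion (population standard deviation)
#'
#' @param ds a [feature_dataset()].
#' @return numeric vector of length q.
#' @export
std_scores <- function(ds) {
  if (nrow(ds$features) < 2) stopf("need at least 2 subjects")
  unname(pop_sd(ds$features))
}

#' Combine filter scores into feature weights
#'
#' Linear combination of Fisher, mutual-information and dispersion scores:
#' \eqn{s_j = \alpha_1 h_j + \alpha_2 m_j + \alpha_3 \sigma_j}.  Because the
#' raw components live on very different scales, each is min-max normalized
#' to \[0, 1\] across features before weighting (set `raw_components = TRUE`
#' for the literal unnormalized combination).
#'
#' @param fisher,mutinfo,stdev component score vectors (equal length q).
#' @param alphas numeric triple summing to 1; default c(0.4, 0.4, 0.2).
#' @param raw_components skip min-max normalization.
#' @return object of class `feature_weight_table`: list with the raw
#'   components, `combined` weights, `rank_order` (feature ids sorted by
#'   decreasing weight, ties broken by smaller id) and `alphas`.
#' @export
combine_weights <- function(fisher, mutinfo, stdev, alphas = c(0.4, 0.4, 0.2),
                            raw_components = FALSE) {
  if (abs(sum(alphas) - 1) > 1e-12)
    stopf("alphas must sum to 1 (got %g)", sum(alphas))
  q <- length(fisher)
  if (length(mutinfo) != q || length(stdev) != q)
    stopf("component vectors must have equal length")
  minmax <- function(v) {
    r <- range(v)
    if (r[2] - r[1] == 0) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  }
  comp <- if (raw_components) list(fisher, mutinfo, stdev)
          else lapply(list(fisher, mutinfo, stdev), minmax)
  combined <- alphas[1] * comp[[1]] + alphas[2] * comp[[2]] + alphas[3] * comp[[3]]
  structure(list(fisher = fisher, mutinfo = mutinfo, stdev = stdev,
                 combined = combined,
                 rank_order = order(-combined, seq_len(q)),
                 alphas = alphas),
            class = "feature_weight_table")
}

#' Compute the full feature weight table for a dataset
#'
#' Convenience wrapper running [fisher_scores()], [mutual_information_scores()],
#' [std_scores()] and [combine_weights()].
#'
#' @inheritParams mutual_information_scores
#' @inheritParams combine_weights
#' @return a `feature_weight_table`.
#' @export
feature_weights <- function(ds, alphas = c(0.4, 0.4, 0.2), n_bins = 10,
                            normalize_mi = FALSE, raw_components = FALSE) {
  combine_weights(fisher_scores(ds),
                  mutual_information_scores(ds, n_bins = n_bins, normalize = normalize_mi),
                  std_scores(ds), alphas = alphas, raw_components = raw_components)
}

#' @export
print.feature_weight_table <- function(x, ...) {
  cat(sprintf("Feature weights for %d features (alpha = %s)\n",
              length(x$combined), paste(x$alphas, collapse = "/")))
  cat("  top 5 features:", paste(utils::head(x$rank_order, 5), collapse = ", "), "\n")
  invisible(x)
}

# perpendicular-distance knee of a curve y over x = 1..length(y):
# distance of each interior point from the chord through the endpoints
knee_of_curve <- function(y, tol = 1e-12) {
  m <- length(y)
  if (m < 3) return(NA_integer_)
  x <- seq_len(m)
  a <- (y[m] - y[1]) / (x[m] - x[1])
  b <- y[1] - a * x[1]
  j <- 2:(m - 1)
  d <- abs(y[j] - (a * x[j] + b)) / sqrt(a^2 + 1)
  if (max(d) < tol) return(NA_integer_)
  j[which.max(d)]
}

#' Knee points of the ranked weight curve
#'
#' Finds up to two knee points on a descending weight curve.  A knee is the
#' interior point at maximal perpendicular distance from the straight line
#' joining the first and last curve points; the second knee applies the
#' same rule to the sub-curve strictly after the first.  The knees cut the
#' ranking into three strata: `core` (ranks before the first knee),
#' `important` (first knee up to, excluding, the second) and `remaining`.
#' Flat or perfectly linear (sub-)curves yield no knee and the strata
#' collapse accordingly.
#'
#' @param weights_sorted numeric weights in decreasing order (length >= 3).
#' @return object of class `knee_partition`: `knee1`, `knee2` (rank
#'   positions, NA when absent) and `strata`, a factor over rank positions
#'   with levels core/important/remaining.
#' @export
detect_knees <- function(weights_sorted) {
  m <- length(weights_sorted)
  if (m < 3) stopf("need at least 3 points to locate a knee")
  k1 <- knee_of_curve(weights_sorted)
  k2 <- NA_integer_
  if (!is.na(k1) && (m - k1) >= 3) {
    sub <- weights_sorted[(k1 + 1):m]
    ks <- knee_of_curve(sub)
    if (!is.na(ks)) k2 <- k1 + ks
  }
  strata <- rep("core", m)
  if (!is.na(k1)) {
    strata[seq_len(m) >= k1] <- "important"
    if (!is.na(k2)) strata[seq_len(m) >= k2] <- "remaining"
  }
  structure(list(knee1 = k1, knee2 = k2,
                 strata = factor(strata, levels = c("core", "important", "remaining"))),
            class = "knee_partition")
}

#' @export
print.knee_partition <- function(x, ...) {
  cat(sprintf("Knee partition: knee1 = %s, knee2 = %s | core %d, important %d, remaining %d\n",
              ifelse(is.na(x$knee1), "none", x$knee1),
              ifelse(is.na(x$knee2), "none", x$knee2),
              sum(x$strata == "core"), sum(x$strata == "important"),
              sum(x$strata == "remaining")))
  invisible(x)
}

#' Stratum label per feature
#'
#' Maps the rank-space strata of [detect_knees()] back onto feature ids.
#'
#' @param table a `feature_weight_table`.
#' @param knees optional precomputed `knee_partition`.
#' @return character vector of length q with the stratum of each feature.
#' @export
feature_strata <- function(table, knees = NULL) {
  knees <- knees %||% detect_knees(table$combined[table$rank_order])
  out <- character(length(table$combined))
  out[table$rank_order] <- as.character(knees$strata)
  out
}

#' Selection probabilities from feature weights
#'
#' Normalizes the combined weights to initial probabilities
#' \eqn{P_j = \omega_j / \sum \omega} and rescales so the best feature has
#' probability one: \eqn{P'_j = P_j / \max P}.  \eqn{P'} is the per-feature
#' inclusion probability used by task generation.
#'
#' @param weights a `feature_weight_table` or a non-negative numeric vector.
#' @return list with `P` (sums to 1) and `P_adj` (max equals 1).
#' @export
selection_probabilities <- function(weights) {
  w <- if (inherits(weights, "feature_weight_table")) weights$combined else weights
  if (any(w < 0)) stopf("weights must be non-negative")
  s <- sum(w)
  if (s <= 0) stopf("all feature weights are zero; cannot form probabilities")
  P <- w / s
  list(P = P, P_adj = P / max(P))
}

#' Generate candidate feature sets for related selection tasks
#'
#' Each task draws a uniform threshold lambda and keeps every feature whose
#' adjusted selection probability clears it (`lambda <= P'_j`), so
#' high-weight features recur across tasks while low-weight features still
#' enter occasionally.  Mode "per_feature_lambda" instead draws an
#' independent lambda per feature (independent Bernoulli inclusion).
#' Tasks that come out empty are redrawn, up to 100 consecutive retries.
#'
#' @param p_adj adjusted selection probabilities (max 1), e.g.
#'   `selection_probabilities(w)$P_adj`.
#' @param n number of tasks (default 8).
#' @param seed integer seed; masks are reproducible given it.
#' @param mode "per_task_lambda" (default, one threshold per task) or
#'   "per_feature_lambda".
#' @return object of class `task_collection`: `masks` (n x q logical
#'   matrix), `lambdas` (per-task draws, NA in per-feature mode), `mode`,
#'   `seed`.
#' @export
generate_tasks <- function(p_adj, n = 8, seed = NULL,
                           mode = c("per_task_lambda", "per_feature_lambda")) {
  mode <- match.arg(mode)
  if (n < 1) stopf("need at least one task")
  q <- length(p_adj)
  with_seed(seed, {
    masks <- matrix(FALSE, n, q)
    lambdas <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      for (try in seq_len(101)) {
        if (try > 100) stopf("100 consecutive empty task draws; check probabilities")
        if (mode == "per_task_lambda") {
          lam <- stats::runif(1)
          mask <- lam <= p_adj
        } else {
          lam <- NA_real_
          mask <- stats::runif(q) <= p_adj
        }
        if (any(mask)) break
      }
      masks[i, ] <- mask
      lambdas[i] <- lam
    }
    structure(list(masks = masks, lambdas = lambdas, mode = mode, seed = seed),
              class = "task_collection")
  })
}

#' @export
print.task_collection <- function(x, ...) {
  cat(sprintf("Task collection: %d tasks over %d features (mode %s)\n",
              nrow(x$masks), ncol(x$masks), x$mode))
  cat("  candidate counts:", paste(rowSums(x$masks), collapse = ", "), "\n")
  invisible(x)
}

#' Tabular weight report
#'
#' @param ds a [feature_dataset()] (for the edge index).
#' @param table a `feature_weight_table`.
#' @return data.frame: feature_id, roi_a, roi_b, fisher, mutinfo, stdev,
#'   combined, rank, stratum.
#' @export
weight_report <- function(ds, table) {
  q <- length(table$combined)
  rank <- integer(q); rank[table$rank_order] <- seq_len(q)
  data.frame(feature_id = seq_len(q),
             roi_a = ds$edge_index$name_a, roi_b = ds$edge_index$name_b,
             fisher = table$fisher, mutinfo = table$mutinfo,
             stdev = table$stdev, combined = table$combined,
             rank = rank, stratum = feature_strata(table),
             stringsAsFactors = FALSE)
}
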