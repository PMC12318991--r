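#' Settings for diverse counterfactual generation
#'
#' @param L number of counterfactual candidates per subject (default 10).
#' @param gamma1 weight of the MAD-scaled proximity term (default 0.5).
#' @param gamma2 weight of the determinant diversity term (default 1).
#' @param target_label class the candidates should be pushed to (default 1,
#'   control: a patient profile is moved toward the classifier's normal
#'   region).
#' @param learning_rate fixed subgradient step size.
#' @param max_iters iteration cap of the descent.
#' @param init_noise_sd sd of the Gaussian jitter around the original
#'   profile used to initialize candidates.
#' @param diag_jitter_scale scale of the uniform diagonal perturbation that
#'   stabilizes the diversity determinant.
#' @param seed integer seed (initialization and jitter).
#' @param clip_range NULL (no box constraints; counterfactual FC values may
#'   leave \[-1, 1\]) or a length-2 numeric range.
#' @param normalize_by "k" (average the proximity over the k features,
#'   default) or "L" (divide by the candidate count instead).
#' @return list of class `cf_control`.
#' @export
cf_control <- function(L = 10, gamma1 = 0.5, gamma2 = 1, target_label = 1,
                       learning_rate = 0.05, max_iters = 1000,
                       init_noise_sd = 0.1, diag_jitter_scale = 1e-4,
                       seed = NULL, clip_range = NULL,
                       normalize_by = c("k", "L")) {
  normalize_by <- match.arg(normalize_by)
  if (L < 1) stopf("L must be at least 1")
  if (gamma1 < 0 || gamma2 < 0) stopf("gamma weights must be non-negative")
  if (!target_label %in% c(0, 1)) stopf("target_label must be 0 or 1")
  structure(list(L = as.integer(L), gamma1 = gamma1, gamma2 = gamma2,
                 target_label = as.integer(target_label),
                 learning_rate = learning_rate, max_iters = as.integer(max_iters),
                 init_noise_sd = init_noise_sd,
                 diag_jitter_scale = diag_jitter_scale, seed = seed,
                 clip_range = clip_range, normalize_by = normalize_by),
            class = "cf_control")
}

#' Median absolute deviations of the selected features
#'
#' Per-feature MAD over the training set, the robust scale used by the
#' counterfactual proximity metric.  A zero MAD falls back to the
#' feature's population standard deviation, then to 1, so the scale is
#' strictly positive; fallbacks are flagged.
#'
#' @param ds training [feature_dataset()] (or list with `features`).
#' @param mask logical or integer selector of features (default: all).
#' @return list with `values` (strictly positive) and `fallback`
#'   (character: "none", "sd" or "unit").
#' @export
compute_mads <- function(ds, mask = NULL) {
  x <- ds$features
  if (!is.null(mask)) x <- x[, if (is.logical(mask)) which(mask) else mask, drop = FALSE]
  if (nrow(x) == 0) stopf("empty training set")
  vals <- apply(x, 2, function(col) stats::median(abs(col - stats::median(col))))
  fb <- rep("none", length(vals))
  zero <- vals == 0
  if (any(zero)) {
    sds <- pop_sd(x[, zero, drop = FALSE])
    vals[zero] <- sds
    fb[zero] <- "sd"
    still <- vals == 0
    vals[still] <- 1
    fb[still] <- "unit"
  }
  list(values = unname(vals), fallback = fb)
}

#' Hinge validity loss of a candidate
#'
#' max(0, 1 - z * logit), where the logit is the classifier's unscaled
#' decision value and z = +1 when the target class is 1 (control), -1 when
#' it is 0.  Zero loss means the candidate sits beyond the unit margin on
#' the target side.
#'
#' @param model a `margin_model`.
#' @param x candidate vector in the model's (selected) feature space.
#' @param target_label 0 or 1.
#' @return non-negative scalar.
#' @export
hinge_loss <- function(model, x, target_label) {
  if (length(x) != length(model$weights))
    stopf("candidate has %d features; model expects %d",
          length(x), length(model$weights))
  z <- if (target_label == 1) 1 else -1
  max(0, 1 - z * (sum(model$weights * x) + model$bias))
}

#' MAD-scaled proximity between a candidate and the original profile
#'
#' Mean over the k selected features of |x - c| / MAD (or sum / L when the
#' control's `normalize_by = "L"`).
#'
#' @param x,c numeric vectors of equal length k.
#' @param mads positive MAD scales (vector or [compute_mads()] result).
#' @param normalize_by "k" or "L"; @param L candidate count for the "L" variant.
#' @return non-negative scalar.
#' @export
proximity <- function(x, c, mads, normalize_by = "k", L = NULL) {
  if (is.list(mads)) mads <- mads$values
  if (length(x) != length(c) || length(x) != length(mads))
    stopf("x, c and mads must have equal length")
  s <- sum(abs(x - c) / mads)
  if (normalize_by == "L") s / L else s / length(x)
}

#' Determinant diversity of a candidate set
#'
#' Builds the similarity kernel K_uv = 1 / (1 + dist(x_u, x_v)) with the
#' MAD-scaled proximity as distance, adds a small seeded uniform jitter on
#' the diagonal to keep the determinant well defined for near-duplicate
#' candidates, and returns det(K).  Distinct candidates give determinants
#' near (0, 1]; duplicates drive it to ~0.
#'
#' @param candidates L x k matrix of candidates (rows).
#' @param mads positive MAD scales.
#' @param jitter_scale uniform jitter range \[0, jitter_scale\] (default 1e-4).
#' @param jitter optional precomputed length-L jitter vector (used by the
#'   optimizer to keep the objective fixed during descent).
#' @return scalar determinant.
#' @export
diversity_det <- function(candidates, mads, jitter_scale = 1e-4, jitter = NULL) {
  if (is.list(mads)) mads <- mads$values
  candidates <- as.matrix(candidates)
  L <- nrow(candidates)
  K <- diag(1, L)
  if (L > 1) {
    for (u in seq_len(L - 1)) for (v in (u + 1):L) {
      K[u, v] <- K[v, u] <- 1 / (1 + proximity(candidates[u, ], candidates[v, ], mads))
    }
  }
  if (is.null(jitter)) jitter <- stats::runif(L, 0, jitter_scale)
  det(K + diag(jitter, L))
}

# Exact gradient of det(K) w.r.t. every candidate coordinate, using
# d det(K) = det(K) * tr(K^{-1} dK) and dK_uv/dx_uj = -K_uv^2 *
# sign(x_uj - x_vj) / (k * mad_j).  Returns NULL when K is numerically
# singular (the caller then skips the diversity step for that iteration).
diversity_gradient <- function(X, mads, jitter) {
  L <- nrow(X); k <- ncol(X)
  K <- diag(1, L)
  for (u in seq_len(L - 1)) for (v in (u + 1):L) {
    K[u, v] <- K[v, u] <- 1 / (1 + proximity(X[u, ], X[v, ], mads))
  }
  Kj <- K + diag(jitter, L)
  detK <- det(Kj)
  Kinv <- tryCatch(solve(Kj), error = function(e) NULL)
  if (is.null(Kinv)) return(NULL)
  G <- matrix(0, L, k)
  for (u in seq_len(L)) {
    others <- setdiff(seq_len(L), u)
    for (v in others) {
      # symmetric entry appears twice in tr(K^{-1} dK)
      coefst <- 2 * detK * Kinv[u, v] * (-K[u, v]^2)
      G[u, ] <- G[u, ] + coefst * sign(X[u, ] - X[v, ]) / (k * mads)
    }
  }
  G
}

#' Combined counterfactual objective
#'
#' total = mean hinge loss + gamma1 * mean proximity - gamma2 *
#' determinant diversity, returned together with its parts.
#'
#' @param model a `margin_model`.
#' @param candidates L x k matrix.
#' @param c original profile (length k).
#' @param mads positive MAD scales.
#' @param control a [cf_control()].
#' @param jitter optional fixed diagonal jitter for the diversity term.
#' @return list(total, hinge, proximity, diversity).
#' @export
cf_objective <- function(model, candidates, c, mads, control, jitter = NULL) {
  if (is.list(mads)) mads <- mads$values
  candidates <- as.matrix(candidates)
  L <- nrow(candidates)
  h <- mean(vapply(seq_len(L), function(l)
    hinge_loss(model, candidates[l, ], control$target_label), numeric(1)))
  pr <- mean(vapply(seq_len(L), function(l)
    proximity(candidates[l, ], c, mads, control$normalize_by, L), numeric(1)))
  dv <- diversity_det(candidates, mads, control$diag_jitter_scale, jitter = jitter)
  list(total = h + control$gamma1 * pr - control$gamma2 * dv,
       hinge = h, proximity = pr, diversity = dv)
}

#' Generate diverse counterfactual examples for one subject
#'
#' Jointly optimizes L candidates initialized by Gaussian perturbation of
#' the subject's selected-feature profile, minimizing the combined
#' objective by fixed-step proximal-subgradient descent: an analytic
#' subgradient for the hinge term, the exact determinant gradient for the
#' diversity term (d det(K) = det(K) tr(K^{-1} dK), with dK/dx given by
#' the kernel's proximity distances), and the exact proximal operator
#' (soft-thresholding toward the original profile) for the L1 proximity
#' term.  The descent stops when every candidate is valid
#' (predicted as the target class) and the relative objective change drops
#' below 1e-5, or at `max_iters`.  Candidate values are unconstrained by
#' default — a counterfactual FC value may leave \[-1, 1\].
#'
#' @param model a `margin_model` trained on the selected features.
#' @param c original profile: vector of length k (the model's feature
#'   space) or a full-length feature vector, which is masked automatically.
#' @param ds_train training [feature_dataset()] (for the MAD scales).
#' @param control a [cf_control()].
#' @return object of class `counterfactual_set`: `original`, `candidates`
#'   (L x k), `valid` (logical), `loss` (objective decomposition),
#'   `iterations`, `mads`, `control`.
#' @export
generate_counterfactuals <- function(model, c, ds_train, control = cf_control()) {
  k <- length(model$weights)
  if (length(c) != k) {
    if (length(c) >= max(model$feature_ids)) c <- c[model$feature_ids]
    else stopf("original profile has %d features; model expects %d", length(c), k)
  }
  mads <- compute_mads(ds_train, mask = model$feature_ids)
  mv <- mads$values
  L <- control$L
  z <- if (control$target_label == 1) 1 else -1
  lr <- control$learning_rate

  with_seed(control$seed, {
    X <- matrix(c, L, k, byrow = TRUE) +
      matrix(stats::rnorm(L * k, 0, control$init_noise_sd), L, k)
    jitter <- stats::runif(L, 0, control$diag_jitter_scale)

    obj <- function(M) cf_objective(model, M, c, mv, control, jitter = jitter)
    cur <- obj(X)
    if (!is.finite(cur$total)) stopf("non-finite objective at initialization")
    prox_den <- if (control$normalize_by == "L") L else k
    iter <- 0L
    repeat {
      iter <- iter + 1L
      # gradients of L * objective: the 1/L averaging is absorbed into the
      # step so the step scale does not shrink with the candidate count
      G <- matrix(0, L, k)
      for (l in seq_len(L)) {
        logit <- sum(model$weights * X[l, ]) + model$bias
        if (1 - z * logit > 0) G[l, ] <- G[l, ] - z * model$weights
      }
      if (control$gamma2 > 0 && L > 1) {
        dG <- diversity_gradient(X, mv, jitter)
        if (!is.null(dG)) G <- G - control$gamma2 * L * dG
      }
      X <- X - lr * G
      # the L1 proximity term is applied through its exact proximal
      # operator (soft-thresholding toward the original profile), which
      # avoids fixed-step oscillation around unchanged features
      thr <- lr * control$gamma1 / (prox_den * mv)
      D <- sweep(X, 2, c)
      X <- sweep(sign(D) * pmax(abs(D) - rep(thr, each = L), 0), 2, c, `+`)
      if (!is.null(control$clip_range))
        X <- pmin(pmax(X, control$clip_range[1]), control$clip_range[2])
      nxt <- obj(X)
      if (!is.finite(nxt$total)) stopf("non-finite objective at iteration %d", iter)
      valid <- predict(model, X) == control$target_label
      rel <- abs(nxt$total - cur$total) / max(abs(cur$total), 1e-12)
      cur <- nxt
      if ((all(valid) && rel < 1e-5) || iter >= control$max_iters) break
    }

    structure(list(original = c, candidates = X,
                   valid = predict(model, X) == control$target_label,
                   loss = cur, iterations = iter, mads = mads,
                   feature_ids = model$feature_ids, control = control),
              class = "counterfactual_set")
  })
}

#' @export
print.counterfactual_set <- function(x, ...) {
  cat(sprintf("Counterfactual set: %d candidates on %d features; %d valid (%.0f%%)\n",
              nrow(x$candidates), ncol(x$candidates), sum(x$valid),
              100 * mean(x$valid)))
  cat(sprintf("  loss: hinge %.4f, proximity %.4f, diversity %.4f (%d iterations)\n",
              x$loss$hinge, x$loss$proximity, x$loss$diversity, x$iterations))
  invisible(x)
}

#' Edge-level change report for a counterfactual set
#'
#' One row per candidate and selected edge: the original FC value, the
#' counterfactual value, their difference and its direction ("increase",
#' "decrease", or "unchanged" when |delta| < 1e-6).
#'
#' @param cfs a `counterfactual_set`.
#' @param edge_index edge index of the full feature space (e.g.
#'   `ds$edge_index`).
#' @return data.frame with columns candidate_id, feature_id, roi_a, roi_b,
#'   original, cf_value, delta, direction; L x k rows.
#' @export
change_report <- function(cfs, edge_index) {
  ids <- cfs$feature_ids
  if (max(ids) > nrow(edge_index)) stopf("edge index misaligned with the feature space")
  L <- nrow(cfs$candidates); k <- ncol(cfs$candidates)
  out <- do.call(rbind, lapply(seq_len(L), function(l) {
    delta <- cfs$candidates[l, ] - cfs$original
    data.frame(candidate_id = l, feature_id = ids,
               roi_a = edge_index$name_a[ids], roi_b = edge_index$name_b[ids],
               original = cfs$original, cf_value = cfs$candidates[l, ],
               delta = delta,
               direction = ifelse(abs(delta) < 1e-6, "unchanged",
                                  ifelse(delta > 0, "increase", "decrease")),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
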