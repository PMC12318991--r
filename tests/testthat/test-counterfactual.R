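# small fitted model + training data shared across the counterfactual tests
cf_fixture <- function(seed = 51, q = 10, p_per_class = 25) {
  ds <- separable_dataset(p_per_class = p_per_class, q = q, sep = 1, gap = 2,
                          noise = 0.5, seed = seed, n_rois = 5)
  model <- train_margin_model(ds, mask = seq_len(3))
  list(ds = ds, model = model)
}

test_that("MAD computation matches the definition with graceful fallbacks", {
  x <- cbind(c(1, 2, 3, 100), rep(7, 4), c(-2, -1, 1, 2))
  ds <- list(features = x)
  m <- compute_mads(ds)
  expect_equal(m$values[1], 1.0)  # median 2.5, deviations (1.5,.5,.5,97.5)
  expect_equal(m$fallback[1], "none")

  # constant feature: MAD and sd both zero -> unit fallback
  expect_equal(m$values[2], 1.0)
  expect_equal(m$fallback[2], "unit")

  # symmetric data: brute-force definition
  expect_equal(m$values[3], median(abs(x[, 3] - median(x[, 3]))))

  set.seed(5)
  v <- rnorm(31)
  expect_equal(compute_mads(list(features = cbind(v)))$values,
               median(abs(v - median(v))))
})

test_that("hinge loss follows the margin geometry", {
  model <- structure(list(weights = c(2), bias = 0, feature_ids = 1L, C = 1),
                     class = "margin_model")
  expect_equal(hinge_loss(model, 1, 1), 0)        # logit 2, satisfied margin
  expect_equal(hinge_loss(model, -0.25, 1), 1.5)  # logit -0.5
  expect_equal(hinge_loss(model, -1.5, 0), 0)     # logit -3, target patient
  expect_error(hinge_loss(model, c(1, 2), 1), "expects")

  # zero hinge loss implies a valid (target-class) prediction
  fx <- cf_fixture()
  for (i in 1:20) {
    set.seed(i)
    x <- rnorm(3)
    if (hinge_loss(fx$model, x, 1) == 0)
      expect_equal(predict(fx$model, matrix(x, 1)), 1L)
  }

  # moving along +z*w strictly decreases the hinge loss until it hits 0
  w <- fx$model$weights
  x0 <- rep(-2, 3)
  losses <- vapply(seq(0, 12, by = 0.5), function(step)
    hinge_loss(fx$model, x0 + step * w / sqrt(sum(w^2)), 1), numeric(1))
  pos <- losses > 0
  expect_true(all(diff(losses[pos]) < 0))
  expect_equal(min(losses), 0)
})

test_that("proximity is the MAD-scaled mean deviation with its symmetries", {
  expect_equal(proximity(c(1, 2), c(0, 0), c(1, 2)), 1.0)
  expect_equal(proximity(c(3, -1), c(3, -1), c(1, 1)), 0)
  # doubling the MADs halves the distance
  set.seed(6)
  x <- rnorm(5); c0 <- rnorm(5); mads <- runif(5, 0.5, 2)
  expect_equal(proximity(x, c0, 2 * mads), proximity(x, c0, mads) / 2)
  # "L" normalizer divides by the candidate count instead of the width
  expect_equal(proximity(x, c0, mads, normalize_by = "L", L = 10),
               proximity(x, c0, mads) * 5 / 10)
  expect_error(proximity(1:3, 1:2, 1:3), "equal length")
})

test_that("determinant diversity has its closed-form values and orderings", {
  mads <- rep(1, 4)
  one <- diversity_det(matrix(0, 1, 4), mads, jitter_scale = 1e-4)
  expect_lt(abs(one - 1), 2e-4)

  dup <- diversity_det(rbind(rep(1, 4), rep(1, 4)), mads, jitter_scale = 1e-4)
  expect_lt(abs(dup), 1e-3)

  # two candidates at proximity distance 1: K = ((1, .5), (.5, 1)), det .75
  pair <- rbind(rep(0, 4), rep(1, 4))
  expect_lt(abs(diversity_det(pair, mads, jitter_scale = 1e-4) - 0.75), 1e-3)

  # replacing a duplicate by a distinct candidate increases diversity
  trio_dup <- rbind(rep(0, 4), rep(0, 4), rep(2, 4))
  trio_distinct <- rbind(rep(0, 4), rep(1, 4), rep(2, 4))
  expect_gt(diversity_det(trio_distinct, mads, jitter = rep(0, 3)),
            diversity_det(trio_dup, mads, jitter = rep(0, 3)))

  # bounded by (0, 1 + O(jitter)] for distinct candidates
  set.seed(8)
  for (i in 1:20) {
    M <- matrix(rnorm(12), 3, 4)
    d <- diversity_det(M, rep(1, 4), jitter = rep(0, 3))
    expect_gt(d, 0)
    expect_lte(d, 1 + 1e-8)
  }
})

test_that("analytic diversity gradient agrees with central differences", {
  set.seed(77)
  for (i in 1:5) {
    L <- sample(2:4, 1); k <- sample(2:5, 1)
    X <- matrix(rnorm(L * k), L, k)
    mads <- runif(k, 0.5, 2)
    jit <- rep(0, L)
    G <- fcselect:::diversity_gradient(X, mads, jit)
    eps <- 1e-6
    for (l in seq_len(L)) for (j in seq_len(k)) {
      Xp <- X; Xp[l, j] <- Xp[l, j] + eps
      Xm <- X; Xm[l, j] <- Xm[l, j] - eps
      fd <- (diversity_det(Xp, mads, jitter = jit) -
             diversity_det(Xm, mads, jitter = jit)) / (2 * eps)
      expect_equal(G[l, j], fd, tolerance = 1e-5)
    }
  }
})

test_that("objective decomposition is exact and respects the gamma limits", {
  fx <- cf_fixture()
  mads <- compute_mads(fx$ds, mask = fx$model$feature_ids)
  ctrl <- cf_control(L = 4, gamma1 = 0.7, gamma2 = 1.3, seed = 2)
  set.seed(3)
  cand <- matrix(rnorm(12), 4, 3)
  c0 <- fx$ds$features[1, fx$model$feature_ids]
  jit <- rep(1e-5, 4)

  parts <- cf_objective(fx$model, cand, c0, mads, ctrl, jitter = jit)
  expect_equal(parts$total,
               parts$hinge + 0.7 * parts$proximity - 1.3 * parts$diversity,
               tolerance = 1e-12)

  ctrl0 <- cf_control(L = 4, gamma1 = 0, gamma2 = 0)
  p0 <- cf_objective(fx$model, cand, c0, mads, ctrl0, jitter = jit)
  hmean <- mean(vapply(1:4, function(l) hinge_loss(fx$model, cand[l, ], 1), numeric(1)))
  expect_equal(p0$total, hmean, tolerance = 1e-12)

  # all candidates equal to an already-valid original: hinge 0, proximity 0
  far <- c0; far[1] <- far[1] + 10
  candid <- matrix(far, 3, 3, byrow = TRUE)
  pid <- cf_objective(fx$model, candid, far, mads, ctrl, jitter = rep(0, 3))
  expect_equal(pid$hinge, 0)
  expect_equal(pid$proximity, 0)
  expect_lt(abs(pid$diversity), 1e-10)
})

test_that("counterfactual generation flips patients with high validity, deterministically", {
  fx <- cf_fixture()
  patients <- which(fx$ds$labels == 0)
  rates <- vapply(1:20, function(s) {
    subj <- patients[(s %% length(patients)) + 1]
    ctrl <- cf_control(L = 10, max_iters = 300, seed = s)
    cfs <- generate_counterfactuals(fx$model, fx$ds$features[subj, ], fx$ds, ctrl)
    mean(cfs$valid)
  }, numeric(1))
  expect_gte(mean(rates), 0.9)

  subj <- patients[1]
  ctrl <- cf_control(L = 5, max_iters = 100, seed = 9)
  a <- generate_counterfactuals(fx$model, fx$ds$features[subj, ], fx$ds, ctrl)
  b <- generate_counterfactuals(fx$model, fx$ds$features[subj, ], fx$ds, ctrl)
  expect_identical(a, b)
  expect_equal(dim(a$candidates), c(5, 3))
})

test_that("stronger proximity weight pulls counterfactuals closer to the original", {
  fx <- cf_fixture()
  subj <- which(fx$ds$labels == 0)[2]
  c_full <- fx$ds$features[subj, ]
  mads <- compute_mads(fx$ds, mask = fx$model$feature_ids)
  mean_prox <- vapply(c(0.1, 0.5, 2.0), function(g1) {
    ctrl <- cf_control(L = 8, gamma1 = g1, max_iters = 200, seed = 4)
    cfs <- generate_counterfactuals(fx$model, c_full, fx$ds, ctrl)
    keep <- cfs$valid
    mean(vapply(which(keep), function(l)
      proximity(cfs$candidates[l, ], cfs$original, mads), numeric(1)))
  }, numeric(1))
  # small gammas can tie at the same hinge-bound equilibrium; equality is
  # up to descent step-size noise
  expect_true(all(diff(mean_prox) <= 1e-3))
})

test_that("change reports enumerate every candidate-edge pair with directions", {
  fx <- cf_fixture()
  subj <- which(fx$ds$labels == 0)[1]
  ctrl <- cf_control(L = 3, max_iters = 50, seed = 11)
  cfs <- generate_counterfactuals(fx$model, fx$ds$features[subj, ], fx$ds, ctrl)
  rep <- change_report(cfs, fx$ds$edge_index)
  expect_equal(nrow(rep), 3 * 3)  # L x k
  expect_true(all(rep$direction %in% c("increase", "decrease", "unchanged")))
  expect_equal(rep$delta, rep$cf_value - rep$original)

  # identical candidate: all rows unchanged
  cfs0 <- cfs
  cfs0$candidates <- matrix(cfs$original, 3, 3, byrow = TRUE)
  rep0 <- change_report(cfs0, fx$ds$edge_index)
  expect_true(all(rep0$direction == "unchanged"))

  # a single perturbed edge yields one directional row
  cfs1 <- cfs0
  cfs1$candidates[1, 2] <- cfs1$original[2] + 0.5
  rep1 <- change_report(cfs1, fx$ds$edge_index)
  expect_equal(sum(rep1$direction == "increase"), 1)
  expect_equal(rep1$delta[rep1$direction == "increase"], 0.5)
})
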