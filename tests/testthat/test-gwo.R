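test_that("coefficient vectors follow the linear decay and stay in bounds", {
  set.seed(1)
  c0 <- coefficient_vectors(0, 100, 5)
  expect_equal(c0$d, 2)
  expect_true(all(abs(c0$A) <= 2))

  cend <- coefficient_vectors(100, 100, 5)
  expect_equal(cend$d, 0)
  expect_equal(cend$A, rep(0, 5))  # A vanishes at t = t_max regardless of r1

  draws <- replicate(2000, {
    cf <- coefficient_vectors(50, 100, 1)
    c(cf$A, cf$C)
  })
  expect_true(all(draws[1, ] >= -1 & draws[1, ] <= 1))  # |A| <= d = 1
  expect_true(all(draws[2, ] >= 0 & draws[2, ] <= 2))

  expect_error(coefficient_vectors(-1, 10, 2), "t must lie")
})

test_that("encircling update converges on unanimous leaders and clips to [0,1]", {
  xstar <- c(1, 0, 1, 0)
  # at t = t_max, A = 0, so one step lands exactly on the leaders' mean
  set.seed(2)
  out <- encircle_update(runif(4), list(xstar, xstar, xstar), t = 10, t_max = 10)
  expect_equal(out, xstar)

  # clipping: with extreme leaders the update cannot escape the unit box
  set.seed(3)
  for (i in 1:50) {
    pos <- encircle_update(runif(4), list(rep(1, 4), rep(0, 4), rep(1, 4)),
                           t = 0, t_max = 10)
    expect_true(all(pos >= 0 & pos <= 1))
  }

  # fixed seed reproduces the trajectory bitwise
  traj <- function() {
    set.seed(7)
    p <- runif(4)
    for (t in 1:5) p <- encircle_update(p, list(xstar, xstar, rep(0.5, 4)), t, 10)
    p
  }
  expect_identical(traj(), traj())
})

test_that("binarization thresholds at 0.5 and is idempotent", {
  expect_equal(binarize(c(0.49, 0.5, 0.51)), c(FALSE, TRUE, TRUE))
  expect_equal(binarize(rep(0, 3)), rep(FALSE, 3))
  b <- binarize(c(0, 1, 1, 0))
  expect_equal(binarize(b * 1.0), b)
})

test_that("fitness combines penalized accuracy and handles the empty mask", {
  ds <- separable_dataset(p_per_class = 12, q = 10, n_rois = 5, seed = 5)
  fold <- rep(1:3, length.out = 24)
  ctrl <- gwo_control(rho = 0.9, pack_size = 4, t_max = 1)

  mask1 <- c(TRUE, rep(FALSE, 9))
  f1 <- subset_fitness(mask1, ds$features, ds$labels, fold, ctrl)
  # perfect separation: ACC = 1, one of ten features selected
  expect_equal(f1, 0.9 * 1 - 0.1 * (1 / 10))

  ctrl1 <- ctrl; ctrl1$rho <- 1
  expect_equal(subset_fitness(mask1, ds$features, ds$labels, fold, ctrl1), 1)

  # equal accuracy, larger subset -> strictly lower fitness for rho < 1
  maskall <- rep(TRUE, 10)
  fall <- subset_fitness(maskall, ds$features, ds$labels, fold, ctrl)
  expect_lt(fall, f1 + 1e-12)

  expect_equal(subset_fitness(rep(FALSE, 10), ds$features, ds$labels, fold, ctrl), -1)
})

test_that("transfer probabilities normalize counts, floor zeros, and signal no history", {
  expect_equal(transfer_probabilities(c(2, 1, 1), floor = 0), c(0.5, 0.25, 0.25))
  expect_equal(transfer_probabilities(c(4, 0, 0), floor = 0.05), c(1, 0.05, 0.05))
  expect_null(transfer_probabilities(c(0, 0, 0)))
})

test_that("pack initialization matches its Bernoulli probabilities", {
  set.seed(12)
  pack <- initialize_pack(rep(1, 20), 6)
  expect_true(all(pack == 1))

  bits <- initialize_pack(rep(0.05, 10000), 1)
  expect_lt(abs(mean(bits) - 0.05), 0.01)

  same <- function() { set.seed(9); initialize_pack(runif(15), 8) }
  expect_identical(same(), same())
})

test_that("GWO task runs are elitist, deterministic, and improve with budget", {
  ds <- separable_dataset(p_per_class = 15, q = 21, n_rois = 7, seed = 6)
  task <- rep(TRUE, 21)
  padj <- rep(0.5, 21)
  ctrl <- fast_gwo()

  r1 <- run_gwo_task(task, ds, ctrl, padj, seed = 11)
  expect_true(all(diff(r1$fitness_trace) >= 0))
  expect_equal(max(r1$fitness_trace), r1$best_fitness)
  expect_true(any(r1$best_mask))

  r2 <- run_gwo_task(task, ds, ctrl, padj, seed = 11)
  expect_identical(r1, r2)

  ctrl_long <- fast_gwo(); ctrl_long$t_max <- 30L
  r3 <- run_gwo_task(task, ds, ctrl_long, padj, seed = 11)
  expect_gte(r3$best_fitness, r1$best_fitness)
})

test_that("best-so-far traces never decrease across 50 seeded runs", {
  ds <- random_dataset(p = 24, n_rois = 6, seed = 13)
  ctrl <- gwo_control(pack_size = 5, t_max = 6)
  ok <- vapply(1:50, function(s) {
    r <- run_gwo_task(rep(TRUE, 15), ds, ctrl, rep(0.5, 15), seed = s)
    all(diff(r$fitness_trace) >= 0)
  }, logical(1))
  expect_true(all(ok))
})

test_that("with rho = 1 and a perfectly separating feature the optimum is reached", {
  wins <- vapply(1:20, function(s) {
    ds <- separable_dataset(p_per_class = 15, q = 45, n_rois = 10, seed = 500 + s)
    ctrl <- gwo_control(pack_size = 15, t_max = 25, rho = 1)
    r <- run_gwo_task(rep(TRUE, 45), ds, ctrl, rep(0.5, 45), seed = s)
    r$best_fitness >= 1 - 1e-12
  }, logical(1))
  expect_gte(sum(wins), 19)
})

test_that("multi-task bookkeeping: knowledge counts, aggregation, determinism", {
  syn <- synthesize_dataset(planted_conditions(seed = 17))
  ds <- syn$dataset
  w <- feature_weights(ds)
  padj <- selection_probabilities(w)$P_adj
  tasks <- generate_tasks(padj, n = 3, seed = 23)
  ctrl <- fast_gwo(seed = 29)

  mt <- run_multitask(tasks, ds, ctrl, p_adj = padj)
  best_masks <- do.call(rbind, lapply(mt$task_results, `[[`, "best_mask"))
  expect_identical(mt$kb_counts, as.integer(colSums(best_masks)))
  expect_equal(mt$selection_frequency, unname(colMeans(best_masks)))
  expect_true(any(mt$aggregated_mask))
  # aggregated subset lies inside the union of task candidate sets
  expect_true(all(which(mt$aggregated_mask) %in% which(colSums(tasks$masks) > 0)))

  mt2 <- run_multitask(tasks, ds, ctrl, p_adj = padj)
  expect_identical(mt, mt2)

  # majority rule on constructed task bests
  agg <- local({
    bm <- rbind(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE))
    colSums(bm) > 3 / 2
  })
  expect_equal(agg, c(TRUE, FALSE, FALSE))

  # single task: aggregation returns that task's best under "majority"
  t1 <- generate_tasks(padj, n = 1, seed = 31)
  m1 <- run_multitask(t1, ds, fast_gwo(seed = 37), p_adj = padj)
  expect_equal(m1$aggregated_mask, m1$task_results[[1]]$best_mask)
})

test_that("GWO selects exclusively planted edges under the study conditions", {
  # the parsimony term makes the minimal sufficient subset optimal, so the
  # meaningful recovery property is precision: every selected edge is planted
  res <- vapply(1:20, function(s) {
    syn <- synthesize_dataset(planted_conditions(seed = 600 + s))
    ds <- syn$dataset
    # candidate set: the 50 top-weighted edges (always includes most planted)
    w <- feature_weights(ds)
    cand <- rep(FALSE, 190)
    cand[w$rank_order[1:50]] <- TRUE
    ctrl <- gwo_control(pack_size = 10, t_max = 12, seed = s)
    r <- run_gwo_task(cand, ds, ctrl, selection_probabilities(w)$P_adj, seed = s)
    sel <- which(r$best_mask)
    c(pure = length(sel) > 0 && all(sel %in% syn$planted),
      any_planted = any(sel %in% syn$planted))
  }, logical(2))
  expect_gte(sum(res["pure", ]), 16)
  expect_equal(sum(res["any_planted", ]), 20)
})

test_that("knowledge transfer lifts the initial fitness of later tasks", {
  gains <- vapply(1:20, function(s) {
    syn <- synthesize_dataset(planted_conditions(seed = 700 + s))
    ds <- syn$dataset
    w <- feature_weights(ds)
    padj <- selection_probabilities(w)$P_adj
    tasks <- generate_tasks(padj, n = 8, seed = s)
    on_ctrl <- gwo_control(pack_size = 6, t_max = 3, seed = s)
    off_ctrl <- on_ctrl; off_ctrl$knowledge_transfer <- FALSE
    init_mean <- function(mt)
      mean(vapply(mt$task_results[-1], `[[`, numeric(1), "init_best_fitness"))
    init_mean(run_multitask(tasks, ds, on_ctrl, p_adj = padj)) -
      init_mean(run_multitask(tasks, ds, off_ctrl, p_adj = padj))
  }, numeric(1))
  expect_gte(sum(gains >= 0), 15)
})
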