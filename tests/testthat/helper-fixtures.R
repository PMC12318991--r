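# Shared fixtures: all built in code, seeded, small.

# random feature dataset with no class structure
random_dataset <- function(p = 30, n_rois = 5, seed = 1) {
  q <- n_rois * (n_rois - 1) / 2
  set.seed(seed)
  feature_dataset(matrix(rnorm(p * q), p, q),
                  labels = rep_len(c(0, 1), p), n_rois = n_rois)
}

# toy dataset where feature `sep` separates the classes perfectly and widely
separable_dataset <- function(p_per_class = 20, q = 30, sep = 1, gap = 5,
                              noise = 1, seed = 1, n_rois = NULL) {
  # q must be a triangular number to pose as edge features
  n_rois <- n_rois %||% ((1 + sqrt(1 + 8 * q)) / 2)
  stopifnot(n_rois == round(n_rois))
  set.seed(seed)
  p <- 2 * p_per_class
  labels <- rep(c(0, 1), each = p_per_class)
  x <- matrix(rnorm(p * q, 0, noise), p, q)
  x[, sep] <- ifelse(labels == 0, -gap, gap) + rnorm(p, 0, 0.1)
  feature_dataset(x, labels, n_rois = n_rois)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard planted-edge study conditions: N = 20 (q = 190), 5 planted edges,
# effect 1.5, noise 0.3, 40 + 40 subjects
planted_conditions <- function(seed, delta = 1.5)
  synthetic_spec(n_rois = 20, n_per_class = c(40, 40), planted_edges = 5,
                 effect_size = delta, noise_sd = 0.3, seed = seed)

# small GWO settings used across tests: sizes chosen for fast, convergent
# runs on the 190-edge synthetic problems
fast_gwo <- function(seed = NULL, ...)
  gwo_control(pack_size = 8, t_max = 10, inner_cv_folds = 3, seed = seed, ...)

# brute-force oracles, deliberately loop-based and independent of the
# vectorized implementations they check
oracle_pop_sd <- function(v) sqrt(sum((v - mean(v))^2) / length(v))

oracle_fisher <- function(x, y) {
  vapply(seq_len(ncol(x)), function(j) {
    a <- x[y == 0, j]; b <- x[y == 1, j]
    abs(mean(a) - mean(b))^2 / (oracle_pop_sd(a)^2 + oracle_pop_sd(b)^2 + 1e-12)
  }, numeric(1))
}

oracle_mi <- function(x, y, n_bins = 10) {
  vapply(seq_len(ncol(x)), function(j) {
    br <- unique(quantile(x[, j], probs = seq(0, 1, length.out = n_bins + 1),
                          names = FALSE))
    z <- cut(x[, j], br, include.lowest = TRUE, labels = FALSE)
    total <- 0
    for (zz in unique(z)) for (yy in unique(y)) {
      pj <- mean(z == zz & y == yy)
      if (pj > 0) total <- total + pj * log(pj / (mean(z == zz) * mean(y == yy)))
    }
    total
  }, numeric(1))
}

oracle_knee <- function(y) {
  m <- length(y)
  a <- (y[m] - y[1]) / (m - 1)
  b <- y[1] - a
  best <- NA_integer_; bestd <- -Inf
  for (j in 2:(m - 1)) {
    d <- abs(y[j] - (a * j + b)) / sqrt(a^2 + 1)
    if (d > bestd + 1e-15) { bestd <- d; best <- j }
  }
  if (bestd < 1e-12) NA_integer_ else best
}

oracle_pearson <- function(u, v) {
  cu <- u - mean(u); cv <- v - mean(v)
  sum(cu * cv) / sqrt(sum(cu^2) * sum(cv^2))
}
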