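#' Train the linear maximum-margin classifier
#'
#' Fits a soft-margin linear SVM (via \pkg{e1071}, `scale = FALSE`, fixed
#' cost `C`) on the masked edge features.  The fitted object exposes the
#' primal weight vector and bias oriented so that the unscaled decision
#' value \eqn{w \cdot x + b \ge 0} predicts class 1 (control) and negative
#' values predict class 0 (patient).
#'
#' @param ds a [feature_dataset()] or list with `features` and `labels`.
#' @param mask logical or integer selector of feature columns.
#' @param C soft-margin cost (default 1).
#' @return object of class `margin_model`: `weights` (length k), `bias`,
#'   `feature_ids` (selected global column indices), `C`.
#' @export
train_margin_model <- function(ds, mask = NULL, C = 1) {
  x <- ds$features; y <- ds$labels
  if (is.null(mask)) mask <- rep(TRUE, ncol(x))
  ids <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(ids) == 0) stopf("empty feature mask")
  if (length(unique(y)) < 2) stopf("training data contain a single class")
  xs <- x[, ids, drop = FALSE]
  fit <- e1071::svm(xs, factor(y, levels = c(0, 1)), kernel = "linear",
                    cost = C, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients the decision value toward whichever class it saw first;
  # normalize so that decision >= 0 <=> predicted class 1 (control)
  if (colnames(fit$decision.values) == "0/1") {
    w <- -w; b <- -b
  }
  structure(list(weights = unname(w), bias = unname(b), feature_ids = ids, C = C),
            class = "margin_model")
}

#' Unscaled decision values of a margin model
#'
#' @param model a `margin_model`.
#' @param x matrix of feature rows in the full feature space, or of width
#'   k = length(model$weights) (already masked); a single vector is
#'   accepted.
#' @return numeric vector w.x + b.
#' @export
decision_values <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  k <- length(model$weights)
  if (ncol(x) != k) {
    if (ncol(x) < max(model$feature_ids))
      stopf("input has %d columns; expected %d selected features or the full feature space",
            ncol(x), k)
    x <- x[, model$feature_ids, drop = FALSE]
  }
  drop(x %*% model$weights) + model$bias
}

#' @param object a `margin_model`.
#' @param newdata feature matrix (full space or masked), or a
#'   [feature_dataset()].
#' @param ... unused.
#' @return integer class labels (0 = patient, 1 = control).
#' @rdname train_margin_model
#' @export
predict.margin_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_dataset")) newdata <- newdata$features
  as.integer(decision_values(object, newdata) >= 0)
}

#' @export
print.margin_model <- function(x, ...) {
  cat(sprintf("Linear margin model on %d features (C = %g), bias %.4f\n",
              length(x$weights), x$C, x$bias))
  invisible(x)
}

#' Confusion counts and derived metrics
#'
#' `confusion_counts()` cross-tabulates truth against prediction with the
#' patient class (label 0) as positive by default — the clinical
#' convention; `positive = 1` flips it.  `confusion_metrics()` converts
#' counts to accuracy, sensitivity TP/(TP+FN) and specificity TN/(TN+FP);
#' an undefined ratio (empty denominator) is returned as NA.
#'
#' @param truth,pred vectors of 0/1 labels.
#' @param positive which label counts as positive (default 0, patient).
#' @return `confusion_counts()`: list(TP, FP, TN, FN);
#'   `confusion_metrics()`: list(acc, sen, spe).
#' @export
confusion_counts <- function(truth, pred, positive = 0) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) stopf("truth and pred lengths differ")
  pos <- truth == positive
  list(TP = sum(pos & pred == positive), FP = sum(!pos & pred == positive),
       TN = sum(!pos & pred != positive), FN = sum(pos & pred != positive))
}

#' @param counts list or vector with TP, FP, TN, FN.
#' @rdname confusion_counts
#' @export
confusion_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stopf("empty confusion table")
  list(acc = (TP + TN) / total,
       sen = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       spe = if (TN + FP > 0) TN / (TN + FP) else NA_real_)
}

# seeded stratified fold assignment; class proportions preserved within 1
stratified_folds <- function(labels, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Nested cross-validated evaluation of the full pipeline
#'
#' Stratified k-fold cross-validation in which, by default, the entire
#' selection pipeline (filter weighting, task generation, multi-task GWO,
#' aggregation) is re-run on each training portion only, so no information
#' from the held-out fold leaks into selection.  `nested = FALSE` runs
#' selection once on the full dataset (leaky; for ablation only).
#'
#' @param ds a [feature_dataset()].
#' @param folds number of folds (default 5).
#' @param seed master seed controlling fold assignment, task generation and
#'   the optimizer.
#' @param alphas,n_tasks,n_bins filter/task-generation settings.
#' @param control a [gwo_control()] for the optimizer.
#' @param nested run selection inside each fold (default TRUE).
#' @param positive positive class for sensitivity/specificity (default 0).
#' @return object of class `cv_report`: data.frame `folds` with per-fold
#'   acc/sen/spe, the means, and the fold assignment.
#' @export
cross_validate_pipeline <- function(ds, folds = 5, seed = NULL,
                                    alphas = c(0.4, 0.4, 0.2), n_tasks = 8,
                                    n_bins = 10, control = gwo_control(),
                                    nested = TRUE, positive = 0) {
  y <- ds$labels
  if (min(table(y)) < folds)
    stopf("need at least %d subjects per class for %d-fold CV", folds, folds)
  fold <- stratified_folds(y, folds, seed = derive_seed(seed, "folds"))

  select_on <- function(sub, fold_tag) {
    w <- feature_weights(sub, alphas = alphas, n_bins = n_bins)
    padj <- selection_probabilities(w)$P_adj
    tasks <- generate_tasks(padj, n = n_tasks,
                            seed = derive_seed(seed, paste0("tasks", fold_tag)))
    ctrl <- control
    ctrl$seed <- derive_seed(seed, paste0("gwo", fold_tag))
    run_multitask(tasks, sub, ctrl, p_adj = padj)
  }

  if (!nested) full_sel <- select_on(ds, "full")

  per_fold <- lapply(seq_len(folds), function(f) {
    tr_idx <- which(fold != f); te_idx <- which(fold == f)
    train <- feature_dataset(ds$features[tr_idx, , drop = FALSE], y[tr_idx],
                             n_rois = ds$n_rois, roi_names = ds$roi_names)
    sel <- if (nested) select_on(train, f) else full_sel
    model <- train_margin_model(train, mask = sel$aggregated_mask)
    pred <- predict(model, ds$features[te_idx, , drop = FALSE])
    m <- confusion_metrics(confusion_counts(y[te_idx], pred, positive = positive))
    c(acc = m$acc, sen = m$sen, spe = m$spe)
  })
  tab <- as.data.frame(do.call(rbind, per_fold))
  tab <- cbind(fold = seq_len(folds), tab)
  structure(list(folds = tab,
                 mean = colMeans(tab[c("acc", "sen", "spe")], na.rm = TRUE),
                 assignment = fold, nested = nested, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s selection)\n",
              nrow(x$folds), if (x$nested) "nested" else "leaky full-data"))
  print(round(x$folds, 4), row.names = FALSE)
  cat(sprintf("mean: ACC %.4f  SEN %.4f  SPE %.4f\n",
              x$mean["acc"], x$mean["sen"], x$mean["spe"]))
  invisible(x)
}

#' Paired two-sided Student t-test
#'
#' Used to compare per-dataset accuracy vectors of two methods.  When every
#' pairwise difference is zero the statistic is reported as (t = 0, p = 1)
#' by convention rather than erroring on zero variance.
#'
#' @param a,b paired numeric vectors of equal length >= 2.
#' @return list(t, p).
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stopf("paired vectors must have equal length")
  if (length(a) < 2) stopf("need at least 2 pairs")
  d <- a - b
  if (all(d == 0)) return(list(t = 0, p = 1))
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Chi-square test of independence for a 2 x 2 table
#'
#' Pearson chi-square without continuity correction (df = 1), as used for
#' cohort sex-ratio comparisons.
#'
#' @param counts 2 x 2 matrix of non-negative counts, or length-4 vector
#'   filled by row.
#' @return list(chi2, p).
#' @export
chi_square_2x2 <- function(counts) {
  m <- if (is.matrix(counts)) counts else matrix(counts, 2, 2, byrow = TRUE)
  if (any(dim(m) != 2)) stopf("need a 2 x 2 table")
  if (any(m < 0)) stopf("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stopf("zero row or column margin")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ht$statistic), p = ht$p.value)
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Student t-test of equal means computed from group means, standard
#' deviations and sizes (pooled variance, df = n1 + n2 - 2), as used for
#' cohort age comparisons where only summaries are printed.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list(t, df, p).
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stopf("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stopf("standard deviations must be non-negative")
  df <- n1 + n2 - 2
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = df, p = 1))
    stopf("zero variance in both groups with unequal means")
  }
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
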