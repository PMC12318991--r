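#' Functional connectivity matrix from ROI time series
#'
#' Computes the Pearson correlation between every pair of region-of-interest
#' (ROI) BOLD time series.  The result is the subject's functional
#' connectivity (FC) matrix: symmetric, unit diagonal, entries in \[-1, 1\].
#'
#' @param timeseries numeric T x N matrix; one column per ROI, one row per
#'   acquisition volume.  Column names, when present, are used as ROI labels.
#' @return an N x N symmetric correlation matrix with unit diagonal.
#' @examples
#' ts <- matrix(rnorm(200), 50, 4)
#' fc <- compute_fc_matrix(ts)
#' all(diag(fc) == 1)
#' @export
compute_fc_matrix <- function(timeseries) {
  timeseries <- as.matrix(timeseries)
  if (!is.numeric(timeseries)) stopf("time series must be numeric")
  if (nrow(timeseries) < 3)
    stopf("need at least 3 time points, got %d", nrow(timeseries))
  sds <- apply(timeseries, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    lab <- colnames(timeseries)[bad] %||% as.character(bad)
    stopf("constant time series for ROI(s): %s", paste(lab, collapse = ", "))
  }
  fc <- stats::cor(timeseries)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc
}

check_fc_matrix <- function(cm, tol = 1e-10) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stopf("connectivity matrix must be square")
  if (max(abs(cm - t(cm))) > tol)
    stopf("connectivity matrix is asymmetric beyond tolerance %g", tol)
  cm
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Extracts the strictly-upper-triangular entries in row-major order over
#' ROI pairs (a, b) with a < b, yielding the q = N(N-1)/2 edge features used
#' throughout the package (4,005 features for the 90-region AAL atlas).
#'
#' @param cm symmetric N x N connectivity matrix.
#' @param roi_names optional character vector of N ROI labels; defaults to
#'   the matrix dimnames or `ROI1..ROIN`.
#' @return list with `values` (length-q numeric) and `edge_index`, a
#'   data.frame with columns `edge_id`, `roi_a`, `roi_b` (1-based ROI
#'   indices) and `name_a`, `name_b`.
#' @seealso [devectorize()] for the inverse.
#' @export
vectorize_upper <- function(cm, roi_names = NULL) {
  cm <- check_fc_matrix(cm)
  n <- nrow(cm)
  if (n < 2) stopf("need at least 2 ROIs")
  roi_names <- roi_names %||% colnames(cm) %||% paste0("ROI", seq_len(n))
  # row-major upper triangle == column-major lower triangle of the transpose
  tm <- t(cm)
  values <- tm[lower.tri(tm)]
  list(values = values, edge_index = make_edge_index(n, roi_names))
}

#' Edge index for an N-ROI network
#'
#' Enumerates unordered ROI pairs (a, b), a < b, in row-major order — the
#' feature ordering used by [vectorize_upper()].
#'
#' @param n_rois number of ROIs.
#' @param roi_names optional ROI labels.
#' @return data.frame with columns edge_id, roi_a, roi_b, name_a, name_b.
#' @export
make_edge_index <- function(n_rois, roi_names = NULL) {
  roi_names <- roi_names %||% paste0("ROI", seq_len(n_rois))
  if (length(roi_names) != n_rois) stopf("roi_names must have length %d", n_rois)
  if (anyDuplicated(roi_names)) stopf("ROI names must be unique")
  a <- rep(seq_len(n_rois - 1), times = (n_rois - 1):1)
  b <- unlist(lapply(seq_len(n_rois - 1), function(i) (i + 1):n_rois))
  data.frame(edge_id = seq_along(a), roi_a = a, roi_b = b,
             name_a = roi_names[a], name_b = roi_names[b],
             stringsAsFactors = FALSE)
}

#' Rebuild a connectivity matrix from an edge vector
#'
#' Inverse of [vectorize_upper()]: places the q = N(N-1)/2 edge values back
#' into a symmetric matrix with unit diagonal.
#'
#' @param v numeric edge vector of length N(N-1)/2.
#' @param n_rois number of ROIs N.
#' @return N x N symmetric matrix with unit diagonal.
#' @export
devectorize <- function(v, n_rois) {
  q <- n_rois * (n_rois - 1) / 2
  if (length(v) != q)
    stopf("edge vector length %d incompatible with %d ROIs (expected %d)",
          length(v), n_rois, q)
  m <- diag(1, n_rois)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Construct a feature dataset of edge features and class labels
#'
#' The central data container: one row per subject, one column per FC edge,
#' with binary diagnosis labels (0 = patient, 1 = control) and the edge-to-
#' ROI-pair index map.
#'
#' @param features p x q numeric matrix of edge weights.
#' @param labels length-p vector coercible to \{0, 1\}.
#' @param n_rois number of ROIs N; q must equal N(N-1)/2.
#' @param roi_names optional length-N ROI labels.
#' @param edge_index optional precomputed edge index (validated if given).
#' @return object of class `feature_dataset` with elements `features`,
#'   `labels`, `edge_index`, `n_rois`, `roi_names`.
#' @export
feature_dataset <- function(features, labels, n_rois, roi_names = NULL,
                            edge_index = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  q <- n_rois * (n_rois - 1) / 2
  if (ncol(features) != q)
    stopf("feature matrix has %d columns but N=%d implies q=%d",
          ncol(features), n_rois, q)
  labels <- coerce_labels(labels)
  if (length(labels) != nrow(features))
    stopf("labels length %d != %d subjects", length(labels), nrow(features))
  if (length(unique(labels)) < 2)
    stopf("both classes (0 = patient, 1 = control) must be present")
  roi_names <- roi_names %||% paste0("ROI", seq_len(n_rois))
  idx <- make_edge_index(n_rois, roi_names)
  if (!is.null(edge_index)) {
    if (nrow(edge_index) != q ||
        any(edge_index$roi_a != idx$roi_a) || any(edge_index$roi_b != idx$roi_b))
      stopf("edge_index does not enumerate every unordered ROI pair in row-major order")
  }
  structure(list(features = features, labels = labels, edge_index = idx,
                 n_rois = n_rois, roi_names = roi_names),
            class = "feature_dataset")
}

coerce_labels <- function(labels) {
  lab <- suppressWarnings(as.integer(as.character(labels)))
  if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
    stopf("labels must be 0 (patient) or 1 (control); got: %s",
          paste(utils::head(unique(labels)), collapse = ", "))
  lab
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("Feature dataset: %d subjects x %d edge features (%d ROIs)\n",
              nrow(x$features), ncol(x$features), x$n_rois))
  cat(sprintf("  classes: %d patients (0), %d controls (1)\n",
              sum(x$labels == 0), sum(x$labels == 1)))
  invisible(x)
}

#' Load a feature dataset from delimited-text files
#'
#' Reads per-subject connectivity matrices (`format = "matrix"`, one N x N
#' file each) or ROI time series (`format = "timeseries"`, one T x N file
#' each, FC computed via [compute_fc_matrix()]), together with a subject
#' table holding `subject_id` and `label` columns.
#'
#' @param subject_files character vector of file paths, one per subject.
#' @param subject_table path to a TSV/CSV with columns subject_id, label,
#'   in the same order as `subject_files`, or a data.frame.
#' @param format "matrix" or "timeseries".
#' @param sep field separator; `"\t"` by default, `","` accepted.
#' @param roi_names optional ROI labels (or path to a one-label-per-line file).
#' @return a [feature_dataset()].
#' @export
load_dataset <- function(subject_files, subject_table, format = c("matrix", "timeseries"),
                         sep = "\t", roi_names = NULL) {
  format <- match.arg(format)
  if (is.character(subject_table)) {
    st <- utils::read.table(subject_table, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  } else st <- as.data.frame(subject_table)
  if (!all(c("subject_id", "label") %in% names(st)))
    stopf("subject table needs columns 'subject_id' and 'label'")
  if (nrow(st) != length(subject_files))
    stopf("%d subject files but %d rows in the subject table",
          length(subject_files), nrow(st))
  if (is.character(roi_names) && length(roi_names) == 1 && file.exists(roi_names))
    roi_names <- readLines(roi_names)

  mats <- lapply(subject_files, function(f) {
    m <- as.matrix(utils::read.table(f, header = FALSE, sep = sep))
    dimnames(m) <- NULL
    m
  })
  if (format == "timeseries") mats <- lapply(mats, compute_fc_matrix)
  ns <- vapply(mats, ncol, integer(1))
  if (length(unique(ns)) > 1) {
    n_mode <- as.integer(names(sort(table(ns), decreasing = TRUE))[1])
    bad <- subject_files[ns != n_mode]
    stopf("inconsistent ROI count across subjects (expected %d): %s",
          n_mode, paste(basename(bad), collapse = ", "))
  }
  feats <- t(vapply(mats, function(m) vectorize_upper(m)$values,
                    numeric(ns[1] * (ns[1] - 1) / 2)))
  feature_dataset(feats, st$label, n_rois = ns[1], roi_names = roi_names)
}

#' Write a feature dataset as a plain-text bundle
#'
#' Creates `features.tsv`, `labels.tsv`, `edge_index.tsv` and
#' `manifest.json` under `path`.  [read_dataset_bundle()] restores the
#' dataset losslessly.
#'
#' @param ds a [feature_dataset()].
#' @param path output directory (created if absent).
#' @param extra named list merged into the manifest (e.g. generator spec).
#' @return `path`, invisibly.
#' @export
save_dataset <- function(ds, path, extra = list()) {
  stopifnot(inherits(ds, "feature_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(ds$features, file.path(path, "features.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(subject_id = seq_along(ds$labels), label = ds$labels),
                     file.path(path, "labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(ds$edge_index, file.path(path, "edge_index.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- c(list(n_rois = ds$n_rois, n_subjects = nrow(ds$features),
                     n_features = ncol(ds$features), roi_names = ds$roi_names,
                     package_version = as.character(utils::packageVersion("fcselect"))),
                extra)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset bundle written by [save_dataset()]
#'
#' @param path bundle directory.
#' @return a [feature_dataset()].
#' @export
read_dataset_bundle <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"), simplifyVector = TRUE)
  feats <- as.matrix(utils::read.table(file.path(path, "features.tsv"), sep = "\t"))
  dimnames(feats) <- NULL
  lab <- utils::read.table(file.path(path, "labels.tsv"), header = TRUE, sep = "\t")
  feature_dataset(feats, lab$label, n_rois = man$n_rois, roi_names = man$roi_names)
}

#' Specification for the synthetic connectome generator
#'
#' Describes a two-class cohort with a small planted set of discriminative
#' edges.  Defaults emulate a compact cohort: 20 ROIs (190 edges), 40
#' patients and 40 controls, 5 planted edges whose class-0 mean is shifted
#' by `effect_size`, all other edges identical class-free noise.
#'
#' @param n_rois number of ROIs N (default 20; N = 90 reproduces the
#'   4,005-edge AAL layout).
#' @param n_per_class integer pair: subjects in class 0 (patients) and
#'   class 1 (controls).
#' @param planted_edges number of discriminative edges D.
#' @param effect_size mean shift added to planted edges in class 0
#'   (dimensionless; in "timeseries" mode the target correlation contrast).
#' @param noise_sd standard deviation of the edge noise (must be > 0).
#' @param mode "features" (edges drawn directly) or "timeseries"
#'   (multivariate-normal ROI series, FC via [compute_fc_matrix()]).
#' @param timeseries_length T, number of volumes in "timeseries" mode.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_rois = 20, n_per_class = c(40, 40),
                           planted_edges = 5, effect_size = 1.5,
                           noise_sd = 0.3, mode = c("features", "timeseries"),
                           timeseries_length = 150, seed = 1) {
  mode <- match.arg(mode)
  q <- n_rois * (n_rois - 1) / 2
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  if (effect_size < 0) stopf("effect_size must be non-negative")
  if (planted_edges > q) stopf("planted_edges (%d) exceeds q = %d", planted_edges, q)
  if (length(n_per_class) != 2 || any(n_per_class < 1))
    stopf("n_per_class must be two positive counts")
  structure(list(n_rois = n_rois, n_per_class = as.integer(n_per_class),
                 planted_edges = as.integer(planted_edges),
                 effect_size = effect_size, noise_sd = noise_sd, mode = mode,
                 timeseries_length = as.integer(timeseries_length),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic two-class connectome dataset
#'
#' In "features" mode every edge is i.i.d. Normal(0, noise_sd^2) in both
#' classes, except the D planted edges, whose class-0 (patient) mean is
#' shifted by +effect_size.  In "timeseries" mode each subject gets a
#' multivariate-normal ROI time series whose population correlation on the
#' planted edges differs between classes by about effect_size (planted
#' pairs are chosen ROI-disjoint so the covariance stays positive
#' definite); FC is then computed per subject.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a [feature_dataset()]) and `planted`
#'   (integer edge ids of the planted discriminative edges).
#' @export
synthesize_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_rois
    q <- n * (n - 1) / 2
    p0 <- spec$n_per_class[1]; p1 <- spec$n_per_class[2]
    p <- p0 + p1
    labels <- c(rep(0L, p0), rep(1L, p1))
    if (spec$mode == "features") {
      planted <- sort(sample.int(q, spec$planted_edges))
      feats <- matrix(stats::rnorm(p * q, 0, spec$noise_sd), p, q)
      feats[labels == 0, planted] <- feats[labels == 0, planted] + spec$effect_size
    } else {
      if (2 * spec$planted_edges > n)
        stopf("timeseries mode needs 2*planted_edges <= n_rois for disjoint pairs")
      rois <- sample.int(n, 2 * spec$planted_edges)
      pairs <- matrix(rois, ncol = 2, byrow = TRUE)
      pairs <- t(apply(pairs, 1, sort))
      idx <- make_edge_index(n)
      planted <- sort(idx$edge_id[match(paste(pairs[, 1], pairs[, 2]),
                                        paste(idx$roi_a, idx$roi_b))])
      r0 <- min(spec$effect_size, 0.9)   # correlations are bounded
      sigma0 <- diag(1, n); sigma1 <- diag(1, n)
      for (i in seq_len(nrow(pairs))) {
        sigma0[pairs[i, 1], pairs[i, 2]] <- sigma0[pairs[i, 2], pairs[i, 1]] <- r0
      }
      feats <- matrix(0, p, q)
      for (s in seq_len(p)) {
        sig <- if (labels[s] == 0) sigma0 else sigma1
        ts <- MASS::mvrnorm(spec$timeseries_length, mu = rep(0, n), Sigma = sig)
        ts <- ts + matrix(stats::rnorm(length(ts), 0, spec$noise_sd),
                          nrow(ts), ncol(ts))
        feats[s, ] <- vectorize_upper(compute_fc_matrix(ts))$values
      }
    }
    list(dataset = feature_dataset(feats, labels, n_rois = n),
         planted = planted, spec = spec)
  })
}
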