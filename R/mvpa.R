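#' Preprocess one task run into classifier samples
#'
#' Applies the decoding preprocessing pipeline to a voxel-by-time
#' matrix: (1) stimulus labels are shifted `shift_volumes` later to
#' compensate the hemodynamic delay (3.675 s at the default 5 volumes
#' and TR 0.735 s); (2) each voxel is linearly detrended over the run
#' (mean preserved); (3) values are converted to percent signal change
#' about the run mean; (4) consecutive volumes within each block are
#' averaged into samples (`design$volumes_per_sample` at a time);
#' (5) rest volumes are dropped; (6) sample order is shuffled with
#' `seed`. The default design yields 60 samples, 30 per class.
#'
#' @param data Voxel-by-time numeric matrix (or one row of
#'   [generate_task_data()] via its `data` list-column).
#' @param design A [task_design()].
#' @param shift_volumes Hemodynamic shift in volumes (default 5).
#' @param seed Integer seed for the sample shuffle.
#' @param detrend_order Polynomial order of the slow-shift removal
#'   (default 1, a linear detrend).
#' @return A list with `samples` (samples-by-voxels matrix), `class`
#'   (factor face/shape), and `category` (factor of the 7 categories).
#' @export
preprocess_run <- function(data, design = task_design(), shift_volumes = 5,
                           seed = 1, detrend_order = 1) {
  stopifnot(is.matrix(data))
  validate_task_design(design)
  Tn <- design$n_volumes
  if (ncol(data) != Tn) {
    stop_sleepsig("invalid_argument",
                  sprintf("data has %d volumes but the design declares %d.",
                          ncol(data), Tn))
  }
  b <- design$blocks
  if (any(b$onset + b$length - 1 + shift_volumes > Tn)) {
    stop_sleepsig("design_overflow",
                  "the hemodynamic shift pushes a block past the end of the run.")
  }
  run_mean <- rowMeans(data)
  if (any(abs(run_mean) < 1e-12)) {
    stop_sleepsig("degenerate_voxel",
                  sprintf("voxel %d has zero run mean; percent signal change is undefined.",
                          which(abs(run_mean) < 1e-12)[1]))
  }
  # per-voxel polynomial detrend (remove the fitted trend, keep the
  # mean), then percent signal change about the run mean
  tgrid <- seq_len(Tn)
  P <- stats::poly(tgrid, degree = detrend_order)   # orthonormal, mean-zero
  detr <- data - (data %*% P) %*% t(P)
  psc <- 100 * (detr - run_mean) / run_mean

  vps <- design$volumes_per_sample
  per_block <- b$length %/% vps
  vols <- unlist(lapply(seq_len(nrow(b)), function(i) {
    (b$onset[i] + shift_volumes):(b$onset[i] + vps * per_block[i] - 1 + shift_volumes)
  }), use.names = FALSE)
  sample_id <- rep(seq_len(sum(per_block)), each = vps)
  samples <- rowsum(t(psc)[vols, , drop = FALSE], sample_id, reorder = FALSE) / vps
  category <- rep(b$category, times = per_block)
  k <- nrow(samples)
  cats <- task_categories()
  class <- cats$class[match(category, cats$category)]
  ord <- withr::with_seed(seed, sample.int(k))
  list(
    samples = samples[ord, , drop = FALSE],
    class = factor(class[ord], levels = c("face", "shape")),
    category = factor(category[ord], levels = cats$category)
  )
}

#' Decode stimulus class from region samples
#'
#' Stratified, seeded 6-fold cross-validation of a linear soft-margin
#' SVM. Fold assignment is canonical: samples are first put in a
#' deterministic order (by class, then lexicographically by value) so
#' the result is invariant to the order the samples arrive in, then
#' shuffled with `seed` within class and dealt round-robin to folds.
#'
#' @param samples Samples-by-voxels matrix.
#' @param labels Binary factor/character class labels.
#' @param n_folds Number of folds (default 6; with the default design
#'   each test fold holds 10 samples, 5 per class).
#' @param seed Integer seed for fold assignment (and the solver).
#' @param cost Soft-margin regularization constant (default 1).
#' @param engine `"dcd"` for the built-in dual coordinate-descent
#'   linear SVM, `"e1071"` for `e1071::svm` (identical fold pipeline;
#'   used as a cross-check).
#' @return An object of class `decoding_result`: list with `accuracy`,
#'   `fold_accuracies`, `n_samples`, `n_folds`.
#' @export
decode_region <- function(samples, labels, n_folds = 6, seed = 1, cost = 1,
                          engine = c("dcd", "e1071")) {
  engine <- match.arg(engine)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop_sleepsig("invalid_labels", "both classes must be present.")
  }
  labels <- droplevels(labels)
  if (nlevels(labels) != 2) {
    stop_sleepsig("invalid_labels", "decoding is binary; got more than 2 classes.")
  }
  n <- nrow(samples)
  stopifnot(length(labels) == n)
  if (min(table(labels)) < n_folds) {
    stop_sleepsig("invalid_labels",
                  "each class must have at least n_folds samples for stratified folds.")
  }
  # canonical order: class first, then lexicographic voxel values, so
  # fold assignment does not depend on incoming sample order
  ord <- do.call(order, c(list(labels), as.data.frame(samples)))
  samples <- samples[ord, , drop = FALSE]
  labels <- labels[ord]
  fold <- integer(n)
  withr::with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  y <- ifelse(labels == levels(labels)[1], 1, -1)
  fold_acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    te <- !tr
    if (engine == "dcd") {
      w <- svm_dcd_train(samples[tr, , drop = FALSE], y[tr], cost, 1.0,
                         1000L, 0.1, stage_seed(seed, f))
      d <- ncol(samples)
      scores <- samples[te, , drop = FALSE] %*% w[seq_len(d)] + w[d + 1]
      pred <- ifelse(scores >= 0, 1, -1)
    } else {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop_sleepsig("invalid_argument", "engine 'e1071' requires the e1071 package.")
      }
      fit <- e1071::svm(samples[tr, , drop = FALSE], factor(y[tr]),
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- as.numeric(as.character(predict(fit, samples[te, , drop = FALSE])))
    }
    fold_acc[f] <- mean(pred == y[te])
  }
  structure(
    list(accuracy = mean(fold_acc), fold_accuracies = fold_acc,
         n_samples = n, n_folds = n_folds),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> accuracy %.3f over %d folds (%d samples)\n",
              x$accuracy, x$n_folds, x$n_samples))
  invisible(x)
}

#' Univariate face-minus-shape contrast
#'
#' Mean over face samples of the voxel-mean signal minus the same for
#' shape samples; the univariate counterpart of the decoder.
#'
#' @inheritParams decode_region
#' @return A single contrast value.
#' @export
univariate_contrast <- function(samples, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop_sleepsig("invalid_labels", "both classes must be present.")
  }
  vm <- rowMeans(samples)
  mean(vm[labels == "face"]) - mean(vm[labels == "shape"])
}

#' Decode every subject-by-region entry of a task dataset
#'
#' Maps [preprocess_run()] + [decode_region()] over the rows of a
#' [generate_task_data()] table.
#'
#' @param task_data Output of [generate_task_data()].
#' @param design A [task_design()]; defaults to the one attached to
#'   `task_data`.
#' @param shift_volumes,n_folds,seed,cost,engine Passed through.
#' @return A tibble `subject_id`, `region_id`, `accuracy`, `n_samples`.
#' @export
decode_cohort <- function(task_data, design = NULL, shift_volumes = 5,
                          n_folds = 6, seed = 1, cost = 1, engine = "dcd") {
  design <- design %||% attr(task_data, "design")
  if (is.null(design)) {
    stop_sleepsig("invalid_argument", "no design attached or supplied.")
  }
  acc <- numeric(nrow(task_data))
  for (i in seq_len(nrow(task_data))) {
    prep <- preprocess_run(task_data$data[[i]], design, shift_volumes,
                           seed = stage_seed(seed, i))
    acc[i] <- decode_region(prep$samples, prep$class, n_folds = n_folds,
                            seed = stage_seed(seed, i), cost = cost,
                            engine = engine)$accuracy
  }
  tibble(subject_id = task_data$subject_id, region_id = task_data$region_id,
         accuracy = acc, n_samples = design$n_samples)
}
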