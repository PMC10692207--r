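#' Representational dissimilarity matrix of a region
#'
#' Averages the voxel samples of each of the seven stimulus categories
#' into a category vector and computes pairwise dissimilarities between
#' the vectors, by default `1 - Pearson correlation` (configurable to
#' Euclidean distance).
#'
#' @param samples Samples-by-voxels matrix (from [preprocess_run()]).
#' @param category_labels Factor/character of the 7 categories, one per
#'   sample.
#' @param metric `"pearson"` (default, dissimilarity `1 - r`) or
#'   `"euclidean"`.
#' @return A symmetric 7x7 matrix with zero diagonal, dimnames the
#'   categories in [task_categories()] order.
#' @export
compute_rdm <- function(samples, category_labels,
                        metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  cats <- task_categories()$category
  category_labels <- as.character(category_labels)
  missing_cats <- setdiff(cats, unique(category_labels))
  if (length(missing_cats) > 0) {
    stop_sleepsig("incomplete_design",
                  paste0("missing categories: ", paste(missing_cats, collapse = ", ")))
  }
  means <- t(vapply(cats, function(cc) {
    colMeans(samples[category_labels == cc, , drop = FALSE])
  }, numeric(ncol(samples))))
  if (metric == "pearson") {
    sds <- apply(means, 1, stats::sd)
    if (any(sds == 0)) {
      stop_sleepsig("undefined_correlation",
                    "a category mean pattern has zero variance; 1 - r is undefined.")
    }
    d <- 1 - stats::cor(t(means))
  } else {
    d <- as.matrix(stats::dist(means))
  }
  diag(d) <- 0
  dimnames(d) <- list(cats, cats)
  d
}

#' Representational connectivity between two regions
#'
#' Pearson correlation between the lower triangles (21 entries) of two
#' regions' RDMs; the second-order, task-condition analogue of
#' functional connectivity.
#'
#' @param rdm_a,rdm_b 7x7 RDMs with identical category ordering.
#' @return Correlation value in \[-1, 1\].
#' @export
representational_connectivity <- function(rdm_a, rdm_b) {
  stopifnot(identical(dim(rdm_a), dim(rdm_b)))
  va <- matrix_to_edges(rdm_a)
  vb <- matrix_to_edges(rdm_b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop_sleepsig("undefined_correlation",
                  "an RDM lower triangle has zero variance.")
  }
  stats::cor(va, vb)
}

#' All-pairs representational connectivity matrix
#'
#' @param rdms List of RDMs, one per region, in region order.
#' @return Symmetric R-by-R matrix with unit diagonal.
#' @export
repconn_matrix <- function(rdms) {
  tri <- vapply(rdms, matrix_to_edges, numeric(nrow(rdms[[1]]) * (nrow(rdms[[1]]) - 1) / 2))
  if (any(apply(tri, 2, stats::sd) == 0)) {
    stop_sleepsig("undefined_correlation",
                  "an RDM lower triangle has zero variance.")
  }
  m <- stats::cor(tri)
  diag(m) <- 1
  m
}

#' Per-subject representational connectivity from task data
#'
#' Preprocesses each subject's regions, computes one RDM per region,
#' and correlates RDM lower triangles across regions.
#'
#' @param task_data Output of [generate_task_data()].
#' @param design,shift_volumes,seed,metric Passed through.
#' @return A named list (by subject) of R-by-R representational
#'   connectivity matrices.
#' @export
repconn_cohort <- function(task_data, design = NULL, shift_volumes = 5,
                           seed = 1, metric = "pearson") {
  design <- design %||% attr(task_data, "design")
  subjects <- unique(task_data$subject_id)
  out <- vector("list", length(subjects))
  names(out) <- subjects
  for (s in seq_along(subjects)) {
    rows <- which(task_data$subject_id == subjects[s])
    rdms <- lapply(rows, function(i) {
      prep <- preprocess_run(task_data$data[[i]], design, shift_volumes,
                             seed = stage_seed(seed, i))
      compute_rdm(prep$samples, prep$category, metric = metric)
    })
    out[[s]] <- repconn_matrix(rdms)
  }
  out
}
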