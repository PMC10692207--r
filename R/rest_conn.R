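#' Region-by-region correlation matrix from resting series
#'
#' Full (Pearson) correlation of region time series.
#'
#' @param region_series Regions-by-time numeric matrix.
#' @return Symmetric R-by-R correlation matrix with unit diagonal.
#' @export
region_correlation_matrix <- function(region_series) {
  stopifnot(is.matrix(region_series))
  if (ncol(region_series) < 3) {
    stop_sleepsig("invalid_argument", "need at least 3 time points.")
  }
  v <- apply(region_series, 1, stats::sd)
  if (any(v == 0)) {
    stop_sleepsig("degenerate_series",
                  sprintf("region %d has zero variance.", which(v == 0)[1]))
  }
  m <- stats::cor(t(region_series))
  diag(m) <- 1
  m
}

#' Row-normalize a connectivity matrix by its diagonal
#'
#' Divides row i by the i-th diagonal entry (seed autocorrelation),
#' then symmetrizes by averaging with the transpose. A symmetric
#' unit-diagonal input passes through unchanged.
#'
#' @param m Square matrix with strictly positive diagonal.
#' @return Normalized, symmetrized matrix (unit diagonal).
#' @export
normalize_rows_by_diagonal <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  d <- diag(m)
  if (any(d <= 0)) {
    stop_sleepsig("invalid_diagonal",
                  sprintf("diagonal entry %d is not positive.", which(d <= 0)[1]))
  }
  out <- m / d
  (out + t(out)) / 2
}

#' Edge-wise association models for resting connectivity
#'
#' One OLS model per edge relating connectivity to the standardized
#' phenotype with the resting covariate set, Bonferroni-adjusted over
#' `m_tests`.
#'
#' @param rest A `rest_data` object, or a subjects-by-edges matrix with
#'   rownames giving subject ids.
#' @param phenotypes Phenotype table.
#' @param phenotype Phenotype column name.
#' @param which_edges `"region"` (default) or `"ic"` when `rest` is a
#'   `rest_data` object.
#' @param m_tests Bonferroni universe; defaults to the number of edge
#'   models times the five phenotypes.
#' @param covariates Optional explicit covariate names.
#' @param fisher_z Model edges on the Fisher-z scale instead of the raw
#'   correlation scale (default `FALSE`, matching full-correlation
#'   inputs).
#' @return Tibble as [map_association()], one row per edge.
#' @export
edge_associations <- function(rest, phenotypes, phenotype,
                              which_edges = c("region", "ic"),
                              m_tests = NULL, covariates = NULL,
                              fisher_z = FALSE) {
  which_edges <- match.arg(which_edges)
  if (inherits(rest, "rest_data")) {
    Y <- if (which_edges == "ic") rest$ic_edges else rest$edges
    rownames(Y) <- rest$subject_id
  } else {
    Y <- as.matrix(rest)
    if (is.null(rownames(Y))) rownames(Y) <- phenotypes$subject_id
  }
  if (is.null(colnames(Y))) colnames(Y) <- paste0("e", seq_len(ncol(Y)))
  if (fisher_z) Y <- atanh(pmin(pmax(Y, -1 + 1e-12), 1 - 1e-12))
  m_tests <- m_tests %||% (5 * ncol(Y))
  map_association(Y, phenotypes, phenotype, modality = "rest",
                  covariates = covariates, adjust = "bonferroni",
                  m_tests = m_tests)
}
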