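#' Brain-wide mean connectivity
#'
#' Mean over the R(R-1)/2 unique off-diagonal pairs of a symmetric
#' connectivity matrix (16,110 pairs at R = 180).
#'
#' @param m Symmetric matrix.
#' @param tol Symmetry tolerance (default 1e-8).
#' @return Scalar mean connectivity.
#' @export
global_mean_connectivity <- function(m, tol = 1e-8) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > tol) {
    stop_sleepsig("invalid_matrix", "matrix is not symmetric within tolerance.")
  }
  mean(matrix_to_edges(m))
}

#' Network-block mean connectivity
#'
#' Mean connectivity within and between the seven networks: block
#' (a, b) averages all unique region pairs with one region in network a
#' and the other in b (within-network blocks use unique pairs inside
#' the network).
#'
#' @param m Symmetric R-by-R connectivity matrix.
#' @param atlas Atlas carrying the network labels.
#' @return An object of class `network_blocks`: symmetric 7x7 matrix
#'   of block means (row/col names the networks).
#' @export
network_block_means <- function(m, atlas) {
  check_atlas(atlas)
  stopifnot(nrow(m) == nrow(atlas))
  nets <- unique(atlas$network)
  out <- matrix(NA_real_, length(nets), length(nets),
                dimnames = list(nets, nets))
  idx <- edge_index(nrow(m))
  vals <- m[cbind(idx$i, idx$j)]
  ni <- atlas$network[idx$i]
  nj <- atlas$network[idx$j]
  for (a in seq_along(nets)) {
    for (b in seq_len(a)) {
      sel <- (ni == nets[a] & nj == nets[b]) | (ni == nets[b] & nj == nets[a])
      if (any(sel)) {
        out[a, b] <- out[b, a] <- mean(vals[sel])
      }
    }
  }
  structure(out, class = c("network_blocks", "matrix"))
}

#' Per-subject global representational connectivity
#'
#' The task-condition counterpart of [global_mean_connectivity()]:
#' averages each subject's representational connectivity matrix over
#' unique region pairs, giving one scalar per subject to feed the same
#' association models as the resting global mean.
#'
#' @param repconn_list List of per-subject R-by-R representational
#'   connectivity matrices (see [repconn_cohort()]).
#' @return Named numeric vector, one value per subject.
#' @export
task_global_connectivity <- function(repconn_list) {
  vapply(repconn_list, global_mean_connectivity, numeric(1))
}

#' Global mean connectivity association with a phenotype
#'
#' OLS of per-subject mean connectivity on the standardized phenotype
#' plus covariates; confidence intervals at p = 0.01 (Bonferroni over
#' the five phenotypes at the 0.05 level).
#'
#' @param global_conn Named numeric vector of per-subject mean
#'   connectivity (names = subject ids) or unnamed in phenotype order.
#' @param phenotypes Phenotype table.
#' @param phenotype Phenotype column.
#' @param modality Covariate preset (`"rest"` or `"task"`).
#' @param conf_level Confidence level (default 0.99).
#' @return One-row tibble: `phenotype`, `beta`, `se`, `t`, `p`,
#'   `ci_low`, `ci_high`.
#' @export
global_association <- function(global_conn, phenotypes, phenotype,
                               modality = "rest", conf_level = 0.99) {
  y <- as.numeric(global_conn)
  if (!is.null(names(global_conn))) {
    idx <- match(names(global_conn), phenotypes$subject_id)
    if (anyNA(idx)) {
      stop_sleepsig("schema", "global_conn names not found in phenotype table.")
    }
    phenotypes <- phenotypes[idx, ]
  }
  Xc <- build_covariates(phenotypes, covariate_set(modality, phenotype))
  zph <- as.numeric(scale(as.numeric(phenotypes[[phenotype]])))
  fit <- fit_ols(y, cbind(phenotype = zph, Xc))
  q <- stats::qt(1 - (1 - conf_level) / 2, fit$df_residual)
  tibble(phenotype = phenotype, beta = fit$beta[["phenotype"]],
         se = fit$se[["phenotype"]], t = fit$t[["phenotype"]],
         p = fit$p[["phenotype"]],
         ci_low = fit$beta[["phenotype"]] - q * fit$se[["phenotype"]],
         ci_high = fit$beta[["phenotype"]] + q * fit$se[["phenotype"]])
}

#' Connectome-based predictive modelling
#'
#' Predicts a phenotype from connectivity edges: (1) covariates are
#' regressed out of every edge (full-sample by default, as the
#' procedure is usually stated; within-fold residualization avoids the
#' small leakage and is available via `residualize = "fold"`);
#' (2) within each training fold, edges whose correlation with the
#' phenotype has p < `sel_p` (strictly) are selected; (3) the selected
#' edges are averaged into one summary feature per subject (signed
#' average); (4) a simple regression of phenotype on the feature is fit
#' on the training fold and applied to the test fold; (5) performance
#' is the Pearson correlation between pooled out-of-fold predictions
#' and the true phenotype. A fold that selects no edge predicts its
#' training mean and is recorded in `empty_folds`.
#'
#' @param edges Subjects-by-edges matrix (or `rest_data`, using its
#'   region edges).
#' @param phenotypes Phenotype table.
#' @param phenotype Phenotype column.
#' @param covariates Covariate names (default: resting set).
#' @param sel_p Selection threshold (default 0.01, strict `<`).
#' @param n_folds Folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param residualize `"full"` (default) or `"fold"`.
#' @param feature `"averaged"` (default: one signed average over all
#'   selected edges) or `"posneg"` (classic CPM: separate means of
#'   positively and negatively correlated selected edges entering a
#'   two-feature regression).
#' @return An object of class `sleepsig_cpm`: list with
#'   `performance_r`, `predictions` (tibble `subject_id`, `fold`,
#'   `predicted`, `observed`), `selected_edges` (list per fold),
#'   `sel_p`, `n_folds`, `empty_folds`.
#' @export
cpm_fit_predict <- function(edges, phenotypes, phenotype,
                            covariates = covariate_set("rest"),
                            sel_p = 0.01, n_folds = 10, seed = 1,
                            residualize = c("full", "fold"),
                            feature = c("averaged", "posneg")) {
  residualize <- match.arg(residualize)
  feature <- match.arg(feature)
  if (inherits(edges, "rest_data")) {
    E <- edges$edges
    rownames(E) <- edges$subject_id
  } else {
    E <- as.matrix(edges)
    if (is.null(rownames(E))) rownames(E) <- phenotypes$subject_id
  }
  idx <- match(rownames(E), phenotypes$subject_id)
  if (anyNA(idx)) {
    stop_sleepsig("schema", "edge matrix subjects not found in phenotype table.")
  }
  tab <- phenotypes[idx, ]
  y <- as.numeric(tab[[phenotype]])
  n <- nrow(E)
  Xc <- build_covariates(tab, covariates)
  if (n < 10 * (ncol(Xc) + 2)) {
    stop_sleepsig("invalid_argument",
                  "need at least 10 * (covariate df + 2) subjects for 10-fold CPM.")
  }
  resid_edges <- function(E, Xc) {
    qr.resid(qr(cbind(1, Xc)), E)
  }
  if (residualize == "full") Er <- resid_edges(E, Xc)

  fold <- withr::with_seed(seed, rep_len(seq_len(n_folds), n)[sample.int(n)])
  pred <- numeric(n)
  selected <- vector("list", n_folds)
  empty_folds <- integer(0)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (residualize == "fold") {
      fitq <- qr(cbind(1, Xc[tr, , drop = FALSE]))
      Etr <- qr.resid(fitq, E[tr, , drop = FALSE])
      cf <- qr.coef(fitq, E[tr, , drop = FALSE])
      Ete <- E[!tr, , drop = FALSE] - cbind(1, Xc[!tr, , drop = FALSE]) %*% cf
    } else {
      Etr <- Er[tr, , drop = FALSE]
      Ete <- Er[!tr, , drop = FALSE]
    }
    ytr <- y[tr]
    r <- suppressWarnings(as.numeric(stats::cor(Etr, ytr)))
    r[is.na(r)] <- 0
    m <- sum(tr)
    tt <- r * sqrt((m - 2) / pmax(1 - r^2, 1e-12))
    pv <- 2 * stats::pt(-abs(tt), m - 2)
    sel <- which(pv < sel_p)
    selected[[f]] <- sel
    if (length(sel) == 0) {
      empty_folds <- c(empty_folds, f)
      pred[!tr] <- mean(ytr)
      next
    }
    if (feature == "posneg") {
      pos <- sel[r[sel] > 0]
      neg <- sel[r[sel] < 0]
      ftr <- cbind(
        pos = if (length(pos)) rowMeans(Etr[, pos, drop = FALSE]) else 0,
        neg = if (length(neg)) rowMeans(Etr[, neg, drop = FALSE]) else 0
      )
      fte <- cbind(
        pos = if (length(pos)) rowMeans(Ete[, pos, drop = FALSE]) else 0,
        neg = if (length(neg)) rowMeans(Ete[, neg, drop = FALSE]) else 0
      )
      keep <- apply(ftr, 2, stats::sd) > 0
      cf <- stats::coef(stats::lm(ytr ~ ftr[, keep, drop = FALSE]))
      pred[!tr] <- cf[1] + fte[, keep, drop = FALSE] %*% cf[-1]
    } else {
      feat_tr <- rowMeans(Etr[, sel, drop = FALSE])
      feat_te <- rowMeans(Ete[, sel, drop = FALSE])
      cf <- stats::coef(stats::lm(ytr ~ feat_tr))
      pred[!tr] <- cf[1] + cf[2] * feat_te
    }
  }
  structure(
    list(performance_r = stats::cor(pred, y),
         predictions = tibble(subject_id = rownames(E), fold = fold,
                              predicted = pred, observed = y),
         selected_edges = selected, sel_p = sel_p, n_folds = n_folds,
         empty_folds = empty_folds),
    class = "sleepsig_cpm"
  )
}

#' @export
print.sleepsig_cpm <- function(x, ...) {
  cat(sprintf("<sleepsig_cpm> r(predicted, observed) = %.3f over %d folds",
              x$performance_r, x$n_folds))
  if (length(x$empty_folds) > 0) {
    cat(sprintf(" (%d fold(s) selected no edge)", length(x$empty_folds)))
  }
  cat("\n")
  invisible(x)
}
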