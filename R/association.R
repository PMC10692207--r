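#' Ordinary least squares with named-column diagnostics
#'
#' QR-based least squares with an explicit singularity check: a
#' rank-deficient design aborts naming the collinear column rather than
#' silently dropping it.
#'
#' @param y Response vector.
#' @param X Design matrix or data frame *without* intercept; an
#'   intercept column is prepended.
#' @return List with `beta`, `se`, `t`, `p` (two-sided, t distribution
#'   with n - k df), `residuals`, `df_residual`.
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  Xi <- cbind(`(Intercept)` = 1, X)
  n <- length(y)
  if (n <= ncol(Xi)) {
    stop_sleepsig("invalid_argument", "need more observations than model terms.")
  }
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qrx$pivot[(qrx$rank + 1):ncol(Xi)]]
    stop_sleepsig("singular_design",
                  paste0("design is rank deficient; collinear column(s): ",
                         paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrx, y)
  res <- qr.resid(qrx, y)
  df <- n - ncol(Xi)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(Xi)
  tval <- beta / se
  list(beta = beta, se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df),
       residuals = res, df_residual = df)
}

# one design, many responses: shared QR, vectorized over columns of Y
fit_ols_multi <- function(Y, X) {
  X <- as.matrix(X)
  Xi <- cbind(`(Intercept)` = 1, X)
  n <- nrow(Y)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qrx$pivot[(qrx$rank + 1):ncol(Xi)]]
    stop_sleepsig("singular_design",
                  paste0("design is rank deficient; collinear column(s): ",
                         paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrx, Y)
  res <- qr.resid(qrx, Y)
  df <- n - ncol(Xi)
  sigma2 <- colSums(res^2) / df
  XtXinv_diag <- diag(chol2inv(qr.R(qrx)))
  se <- sqrt(outer(XtXinv_diag, sigma2))
  rownames(se) <- colnames(Xi)
  tval <- beta / se
  list(beta = beta, se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df),
       residuals = res, df_residual = df)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
adjust_fdr_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_sleepsig("invalid_argument", "p-values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment with an explicit test count
#'
#' `min(1, p * m)`, with `m` decoupled from `length(p)` so that e.g.
#' edge-wise maps can be corrected for phenotypes x components.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param m Number of tests (>= 1).
#' @return Adjusted p-values.
#' @export
adjust_bonferroni <- function(p, m) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_sleepsig("invalid_argument", "p-values must lie in [0, 1].")
  }
  check_number(m, "m", min = 1)
  pmin(1, p * m)
}

#' Covariate sets per modality
#'
#' The second-level covariate list depends on the outcome modality:
#' task models include head motion and the task performance statistics,
#' resting models include head motion but not task performance, and
#' anatomical (thickness) models include neither. Imaging models all
#' carry a sex-by-age interaction; the accelerometry time offset enters
#' only models of the accelerometer phenotype (`sleep_bout_h`). The
#' phenotype-correlation stage uses `"pheno"`: no motion, no task
#' statistics, no interaction.
#'
#' @param modality One of `"task"`, `"rest"`, `"anat"`, `"pheno"`.
#' @param phenotype Phenotype the model targets (controls the
#'   accelerometry-offset rule); `NULL` omits the offset.
#' @return Character vector of covariate column names; `"sex:age"`
#'   denotes the interaction.
#' @export
covariate_set <- function(modality = c("task", "rest", "anat", "pheno"),
                          phenotype = NULL) {
  modality <- match.arg(modality)
  base <- c("sex", "age", "site", "ses", "education", "ethnicity")
  cov <- switch(modality,
    task = c(base, "head_motion", "task_acc_mean", "task_rt_mean",
             "task_rt_sd", "sex:age"),
    rest = c(base, "head_motion", "sex:age"),
    anat = c(base, "sex:age"),
    pheno = base
  )
  if (!is.null(phenotype) && identical(phenotype, "sleep_bout_h")) {
    cov <- c(cov, "accel_time_offset")
  }
  cov
}

# expand covariate names into a numeric design matrix: one-hot for
# categorical columns (dropping the first level), ordinals as numeric
# scores, "a:b" as products of the standardized mains
build_covariates <- function(phenotypes, covariates) {
  if (length(covariates) == 0) {
    return(matrix(numeric(0), nrow = nrow(phenotypes), ncol = 0))
  }
  cols <- list()
  for (cv in covariates) {
    if (grepl(":", cv, fixed = TRUE)) {
      parts <- strsplit(cv, ":", fixed = TRUE)[[1]]
      v <- as.numeric(phenotypes[[parts[1]]]) * as.numeric(phenotypes[[parts[2]]])
      cols[[cv]] <- v
      next
    }
    if (!cv %in% names(phenotypes)) {
      stop_sleepsig("schema", paste0("covariate column missing: ", cv))
    }
    v <- phenotypes[[cv]]
    if (is.character(v) || is.factor(v)) {
      v <- droplevels(factor(v))
      if (nlevels(v) < 2) next   # constant in this (sub)sample; nothing to adjust
      mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, substring(colnames(mm), 2))
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    } else {
      cols[[cv]] <- as.numeric(v)
    }
  }
  do.call(cbind, cols)
}

#' Second-level association map
#'
#' Fits one OLS model per unit (region or edge): outcome on the
#' standardized phenotype plus the modality covariates, and reports the
#' phenotype coefficient. For task maps, coefficients can be normalized
#' by the classification error: `beta / max(1 - accuracy, floor)`,
#' up-weighting regions whose voxels respond reliably to the stimuli.
#'
#' @param outcome Long tibble with columns `subject_id`, `unit`,
#'   `value` (one row per subject-unit), or a subjects-by-units matrix
#'   with rownames matching `phenotypes$subject_id`.
#' @param phenotypes Phenotype/covariate table.
#' @param phenotype Name of the phenotype column to model.
#' @param modality Covariate preset, see [covariate_set()].
#' @param covariates Explicit covariate names overriding the preset.
#' @param accuracy_by_unit Optional tibble `unit`, `accuracy` (region
#'   mean decoding accuracy) enabling `beta_normalized`.
#' @param error_floor Smallest admissible classification error
#'   (default `1/(2 * 60)`, i.e. half a sample at 60 samples).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param m_tests Test count for Bonferroni; defaults to the number of
#'   units.
#' @return A tibble `unit`, `phenotype`, `beta`, `se`, `t`, `p`,
#'   `p_adjusted`, and `beta_normalized` when accuracies are supplied.
#' @export
map_association <- function(outcome, phenotypes, phenotype,
                            modality = "task", covariates = NULL,
                            accuracy_by_unit = NULL,
                            error_floor = 1 / 120,
                            adjust = c("BH", "bonferroni"),
                            m_tests = NULL) {
  adjust <- match.arg(adjust)
  if (!phenotype %in% names(phenotypes)) {
    stop_sleepsig("schema", paste0("phenotype column missing: ", phenotype))
  }
  if (is.matrix(outcome)) {
    Y <- outcome
    if (is.null(rownames(Y))) rownames(Y) <- phenotypes$subject_id
  } else {
    req <- c("subject_id", "unit", "value")
    if (!all(req %in% names(outcome))) {
      stop_sleepsig("schema", "outcome needs columns subject_id, unit, value.")
    }
    wide <- tidyr::pivot_wider(outcome, id_cols = "subject_id",
                               names_from = "unit", values_from = "value")
    Y <- as.matrix(wide[-1])
    rownames(Y) <- wide$subject_id
  }
  idx <- match(rownames(Y), phenotypes$subject_id)
  if (anyNA(idx)) {
    stop_sleepsig("schema", "outcome contains subjects absent from the phenotype table.")
  }
  ph_tab <- phenotypes[idx, ]
  covariates <- covariates %||% covariate_set(modality, phenotype)
  Xc <- build_covariates(ph_tab, covariates)
  zph <- as.numeric(scale(as.numeric(ph_tab[[phenotype]])))
  X <- cbind(phenotype = zph, Xc)
  fit <- fit_ols_multi(Y, X)
  out <- tibble(
    unit = colnames(Y) %||% as.character(seq_len(ncol(Y))),
    phenotype = phenotype,
    beta = fit$beta["phenotype", ],
    se = fit$se["phenotype", ],
    t = fit$t["phenotype", ],
    p = fit$p["phenotype", ]
  )
  out$p_adjusted <- if (adjust == "BH") {
    adjust_fdr_bh(out$p)
  } else {
    adjust_bonferroni(out$p, m_tests %||% nrow(out))
  }
  if (!is.null(accuracy_by_unit)) {
    acc <- accuracy_by_unit$accuracy[match(out$unit, as.character(accuracy_by_unit$unit))]
    out$beta_normalized <- out$beta / pmax(1 - acc, error_floor)
  }
  out
}

#' Association maps for all five phenotypes
#'
#' @inheritParams map_association
#' @return Row-bound tibble of [map_association()] results, one block
#'   per phenotype.
#' @export
map_association_all <- function(outcome, phenotypes, modality = "task",
                                accuracy_by_unit = NULL, adjust = "BH",
                                m_tests = NULL, error_floor = 1 / 120) {
  dplyr::bind_rows(lapply(phenotype_names(), function(ph) {
    map_association(outcome, phenotypes, ph, modality = modality,
                    accuracy_by_unit = accuracy_by_unit, adjust = adjust,
                    m_tests = m_tests, error_floor = error_floor)
  }))
}
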