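#' Correlation between two neural signature maps
#'
#' A neural signature is the vector of second-level coefficients (one
#' per region or edge) relating a brain measure to a phenotype; this is
#' their Pearson correlation across units.
#'
#' @param map_a,map_b Numeric coefficient vectors in identical unit
#'   order, length >= 3.
#' @return Correlation value.
#' @export
signature_correlation <- function(map_a, map_b) {
  map_a <- as.numeric(map_a)
  map_b <- as.numeric(map_b)
  if (length(map_a) != length(map_b) || length(map_a) < 3) {
    stop_sleepsig("invalid_argument",
                  "maps must have equal length >= 3.")
  }
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop_sleepsig("undefined_correlation", "a map has zero variance.")
  }
  stats::cor(map_a, map_b)
}

#' Parametric p-value for a signature correlation
#'
#' Two-sided p-value from the exact null distribution of the Pearson
#' coefficient over `n` independent units:
#' `(1 + r) / 2 ~ Beta((n - 2) / 2, (n - 2) / 2)`, `p = 2 min(F, 1 - F)`.
#' Equivalent to the classical t transform
#' `t = r sqrt((n - 2) / (1 - r^2))`.
#'
#' @param r Correlation value.
#' @param n Number of units (>= 4).
#' @return Two-sided p-value.
#' @export
pearson_p_beta <- function(r, n) {
  if (!is.numeric(n) || n < 4) {
    stop_sleepsig("insufficient_sample", "need n >= 4 units.")
  }
  beta_null_p(r, n - 2)
}

# uniform random 3D rotation (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(q)
  Q <- Q %*% diag(sign(diag(qr.R(q))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spatial spin-test p-value for a signature correlation
#'
#' Permutation null that preserves cortical spatial autocorrelation:
#' each permutation draws one uniform 3D rotation, applies it to the
#' left-hemisphere centroids and its x-mirrored version to the right
#' ones, reassigns every region the `map_a` value of the region whose
#' rotated centroid lands nearest its original centroid (per
#' hemisphere, duplicates allowed), averages the two hemispheres'
#' reassignments (regions are bilateral), and recomputes the
#' correlation with `map_b`. The p-value is the fraction of
#' permutations with `|r_perm| >= |r_obs|` (no +1 correction). A
#' label-permutation fallback that ignores geometry is available via
#' `method = "label"`.
#'
#' @param map_a,map_b Coefficient vectors over the atlas regions.
#' @param atlas Atlas with left/right centroids.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param method `"rotation"` (default) or `"label"`.
#' @return List with `p_spin`, `r_obs`, and `r_perm` (length
#'   `n_perm`).
#' @export
spin_test <- function(map_a, map_b, atlas, n_perm = 1000, seed = 1,
                      method = c("rotation", "label")) {
  method <- match.arg(method)
  check_atlas(atlas)
  map_a <- as.numeric(map_a)
  map_b <- as.numeric(map_b)
  R <- nrow(atlas)
  if (length(map_a) != R || length(map_b) != R) {
    stop_sleepsig("atlas_incomplete",
                  "maps must have one value per atlas region.")
  }
  r_obs <- signature_correlation(map_a, map_b)
  L <- as.matrix(atlas[c("x_left", "y_left", "z_left")])
  Rt <- as.matrix(atlas[c("x_right", "y_right", "z_right")])
  M <- diag(c(-1, 1, 1))
  r_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      if (method == "label") {
        perm <- sample.int(R)
        return(stats::cor(map_a[perm], map_b))
      }
      Q <- random_rotation()
      Qm <- M %*% Q %*% M   # mirrored rotation for the right hemisphere
      rotL <- L %*% t(Q)
      rotR <- Rt %*% t(Qm)
      # region j receives the value of the region whose rotated
      # centroid is nearest j's original centroid (duplicates allowed)
      nnL <- max.col(-dist_sq(L, rotL), ties.method = "first")
      nnR <- max.col(-dist_sq(Rt, rotR), ties.method = "first")
      spun <- (map_a[nnL] + map_a[nnR]) / 2
      if (stats::sd(spun) == 0) return(0)
      stats::cor(spun, map_b)
    }, numeric(1))
  })
  list(p_spin = mean(abs(r_perm) >= abs(r_obs)), r_obs = r_obs,
       r_perm = r_perm)
}

# squared Euclidean distances between rows of A and rows of B
dist_sq <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  outer(an, bn, "+") - 2 * tcrossprod(A, B)
}

#' Pairwise signature correlations with dual inference
#'
#' Correlates the coefficient maps of all phenotype pairs and attaches
#' the parametric beta-distribution p-value and, for region-based maps
#' with an atlas, the spin-test p-value. Significance requires both
#' tests below `alpha / 5` (Bonferroni over five phenotypes) when the
#' spin test is run, else the parametric test alone.
#'
#' @param maps Tibble from [map_association_all()] (columns `unit`,
#'   `phenotype`, `beta`), or a units-by-phenotypes matrix.
#' @param atlas Optional atlas enabling the spin test (region maps
#'   only).
#' @param n_perm,seed,spin_method Passed to [spin_test()].
#' @param alpha Family alpha (default 0.05; per-pair threshold
#'   `alpha / 5`).
#' @return An object of class `signature_corr`: tibble `phenotype_a`,
#'   `phenotype_b`, `r`, `n_units`, `p_beta`, `p_spin`, `significant`.
#' @export
signature_correlations <- function(maps, atlas = NULL, n_perm = 1000,
                                   seed = 1, spin_method = "rotation",
                                   alpha = 0.05) {
  if (!is.matrix(maps)) {
    req <- c("unit", "phenotype", "beta")
    if (!all(req %in% names(maps))) {
      stop_sleepsig("schema", "maps need columns unit, phenotype, beta.")
    }
    wide <- tidyr::pivot_wider(maps[req], names_from = "phenotype",
                               values_from = "beta")
    maps <- as.matrix(wide[-1])
    rownames(maps) <- wide$unit
  }
  phs <- colnames(maps)
  pairs <- utils::combn(phs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    r <- signature_correlation(maps[, a], maps[, b])
    p_beta <- pearson_p_beta(r, nrow(maps))
    p_spin <- NA_real_
    if (!is.null(atlas)) {
      p_spin <- spin_test(maps[, a], maps[, b], atlas, n_perm = n_perm,
                          seed = stage_seed(seed, j),
                          method = spin_method)$p_spin
    }
    tibble(phenotype_a = a, phenotype_b = b, r = r,
           n_units = nrow(maps), p_beta = p_beta, p_spin = p_spin)
  })
  out <- dplyr::bind_rows(rows)
  thr <- alpha / 5
  out$significant <- out$p_beta < thr &
    (is.na(out$p_spin) | out$p_spin < thr)
  class(out) <- c("signature_corr", class(out))
  out
}

#' Assign cohort strata
#'
#' Splits the cohort by depression (`phq2 >= 3` is "depressed") or by
#' sleep-bout duration (`sleep_bout_h >= 6.8` hours is
#' "long_sleepers").
#'
#' @param phenotypes Phenotype table.
#' @param variable `"phq2"` or `"sleep_bout_h"`.
#' @param threshold Split point; defaults 3 (phq2) and 6.8 h (sleep).
#' @return Character vector of stratum labels, one per subject.
#' @export
stratify_cohort <- function(phenotypes, variable = c("phq2", "sleep_bout_h"),
                            threshold = NULL) {
  variable <- match.arg(variable)
  if (variable == "phq2") {
    threshold <- threshold %||% 3
    ifelse(phenotypes$phq2 >= threshold, "depressed", "not_depressed")
  } else {
    threshold <- threshold %||% 6.8
    ifelse(phenotypes$sleep_bout_h >= threshold, "long_sleepers",
           "short_sleepers")
  }
}

#' Signature correlations within cohort strata
#'
#' Refits the edge-wise association models of all five phenotypes
#' within each stratum and recomputes the pairwise signature
#' correlations, reproducing the stratified re-analysis (depressed vs
#' not-depressed; long vs short sleepers).
#'
#' @param rest A `rest_data` object (or subjects-by-edges matrix).
#' @param phenotypes Phenotype table (same subjects, same order).
#' @param variable,threshold Passed to [stratify_cohort()].
#' @param min_df_margin Minimum stratum size beyond the model df
#'   (default 10).
#' @return Tibble of `signature_correlations()` rows with a leading
#'   `stratum` column.
#' @export
stratified_signatures <- function(rest, phenotypes,
                                  variable = c("phq2", "sleep_bout_h"),
                                  threshold = NULL, min_df_margin = 10) {
  variable <- match.arg(variable)
  strata <- stratify_cohort(phenotypes, variable, threshold)
  levels <- if (variable == "phq2") {
    c("depressed", "not_depressed")
  } else {
    c("long_sleepers", "short_sleepers")
  }
  Y <- if (inherits(rest, "rest_data")) rest$edges else as.matrix(rest)
  out <- lapply(levels, function(st) {
    keep <- strata == st
    if (sum(keep) == 0) {
      stop_sleepsig("stratification", paste0("stratum is empty: ", st))
    }
    tab <- phenotypes[keep, ]
    Xc <- build_covariates(tab, covariate_set("rest"))
    if (sum(keep) < ncol(Xc) + 2 + min_df_margin) {
      stop_sleepsig("stratification",
                    sprintf("stratum %s has too few subjects (%d) for the model.",
                            st, sum(keep)))
    }
    Ys <- Y[keep, , drop = FALSE]
    rownames(Ys) <- tab$subject_id
    maps <- map_association_all(Ys, tab, modality = "rest",
                                adjust = "bonferroni", m_tests = 5 * ncol(Ys))
    sc <- signature_correlations(maps)
    dplyr::bind_cols(tibble(stratum = st), sc)
  })
  dplyr::bind_rows(out)
}
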