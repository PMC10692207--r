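#' Default phenotype partial-correlation targets
#'
#' The pairwise partial-correlation structure the cohort generator is
#' calibrated to reproduce: depression (PHQ-2) with insomnia 0.15,
#' sleep-bout duration with insomnia -0.072, with dozing -0.11, and with
#' cognition 0.036, insomnia with dozing 0.081; all remaining pairs 0.
#'
#' @return A symmetric 5x5 matrix with unit diagonal, rows/columns in
#'   [phenotype_names()] order.
#' @export
default_phenotype_corr <- function() {
  ph <- phenotype_names()
  m <- diag(5)
  dimnames(m) <- list(ph, ph)
  set_pair <- function(m, a, b, v) {
    m[a, b] <- v
    m[b, a] <- v
    m
  }
  m <- set_pair(m, "sleep_bout_h", "insomnia", -0.072)
  m <- set_pair(m, "sleep_bout_h", "dozing", -0.11)
  m <- set_pair(m, "sleep_bout_h", "cognition", 0.036)
  m <- set_pair(m, "insomnia", "dozing", 0.081)
  m <- set_pair(m, "insomnia", "phq2", 0.15)
  m
}

# latent Gaussian correlations calibrated (calibrate_latent_corr, n = 4e5,
# 12 sweeps, seed 20260924) so that the observed-scale partial correlations
# after the marginal transforms of default_marginals() hit
# default_phenotype_corr() within +/- 0.01 at n = 1e5
default_latent_corr_values <- function() {
  ph <- phenotype_names()
  m <- diag(5)
  dimnames(m) <- list(ph, ph)
  set_pair <- function(m, a, b, v) {
    m[a, b] <- v
    m[b, a] <- v
    m
  }
  m <- set_pair(m, "sleep_bout_h", "insomnia", -0.0789)
  m <- set_pair(m, "sleep_bout_h", "dozing", -0.1465)
  m <- set_pair(m, "sleep_bout_h", "cognition", 0.0350)
  m <- set_pair(m, "insomnia", "dozing", 0.1153)
  m <- set_pair(m, "insomnia", "phq2", 0.1953)
  m
}

#' Marginal distributions of the five phenotypes
#'
#' Describes how latent standard-normal scores are mapped to observed
#' phenotype scales: an affine map for sleep-bout hours (mean 6.8 h,
#' the population median split point, sd 1 h), threshold discretization
#' for the ordinal self-reports (insomnia and dozing 0-3, PHQ-2 0-6,
#' with about 3% of subjects at PHQ-2 >= 3), and a rounded Gaussian
#' count for the symbol-digit cognition score (mean 19, sd 5).
#'
#' @return Named list of marginal descriptors used by
#'   [generate_phenotypes()] and [calibrate_latent_corr()].
#' @export
default_marginals <- function() {
  list(
    sleep_bout_h = list(type = "affine", mean = 6.8, sd = 1),
    insomnia = list(type = "ordinal", probs = c(0.25, 0.35, 0.25, 0.15)),
    dozing = list(type = "ordinal", probs = c(0.75, 0.18, 0.05, 0.02)),
    phq2 = list(type = "ordinal",
                probs = c(0.64, 0.21, 0.12, 0.015, 0.008, 0.004, 0.003)),
    cognition = list(type = "count", mean = 19, sd = 5)
  )
}

apply_marginal <- function(z, marg) {
  switch(marg$type,
    affine = marg$mean + marg$sd * z,
    ordinal = {
      cuts <- stats::qnorm(cumsum(marg$probs[-length(marg$probs)]))
      findInterval(z, cuts)
    },
    count = pmax(0, round(marg$mean + marg$sd * z)),
    stop_sleepsig("invalid_argument", paste0("unknown marginal type: ", marg$type))
  )
}

#' Specify the planted effect structure of a synthetic cohort
#'
#' Collects every knob of the cohort generator: the target phenotype
#' partial-correlation matrix, the latent Gaussian correlations that
#' realize it after marginal discretization, per-phenotype couplings of
#' the task decoding-signal amplitude, of resting connectivity (global
#' and optionally per edge), and of cortical thickness, plus the noise
#' model of the task voxel data.
#'
#' Default couplings plant the direction pattern the analyses probe:
#' task signal rises with sleep-bout duration and cognition and falls
#' with depression, insomnia, and dozing, while resting connectivity
#' rises with sleep-bout duration, insomnia, and depression (task-hypo
#' / rest-hyper for the sleep-depression pair).
#'
#' @param phenotype_corr Target 5x5 partial-correlation matrix
#'   (symmetric, unit diagonal, positive definite).
#' @param latent_corr Latent Gaussian correlation matrix; `NULL` uses
#'   the precalibrated matrix when `phenotype_corr` is the default, and
#'   otherwise triggers on-the-fly calibration in
#'   [generate_phenotypes()].
#' @param marginals Marginal descriptors, see [default_marginals()].
#' @param task_coupling Named numeric: slope of decoding-signal
#'   amplitude per SD of each phenotype (noise-sd units).
#' @param task_a0 Baseline decoding-signal amplitude (noise-sd units).
#' @param rest_global_coupling Named numeric: slope on mean resting
#'   connectivity (Fisher-z units per phenotype SD).
#' @param rest_edge_coupling Optional edges-by-5 matrix of per-edge
#'   slopes (Fisher-z units per SD); `NULL` means zero.
#' @param thickness_coupling Named numeric: cortical thickness slope
#'   (mm per phenotype SD).
#' @param covariate_leakage Slope of a linear age leakage added to every
#'   phenotype's latent score before the marginal transform (0 disables;
#'   partialling on covariates removes most but not all of it once the
#'   ordinals are discretized).
#' @param voxel_noise_sd,ar1,drift_amplitude Task voxel noise model:
#'   innovation sd, AR(1) coefficient, and amplitude of a slow
#'   sinusoidal drift.
#' @param baseline_signal Mean raw voxel intensity (percent-signal-change
#'   reference level).
#' @param rest_noise_sd Subject-level edge noise sd (Fisher-z units).
#' @param thickness_noise_sd Residual thickness sd (mm).
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(phenotype_corr = default_phenotype_corr(),
                          latent_corr = NULL,
                          marginals = default_marginals(),
                          task_coupling = c(sleep_bout_h = 0.25, insomnia = -0.1,
                                            dozing = -0.1, phq2 = -0.25,
                                            cognition = 0.15),
                          task_a0 = 0.4,
                          rest_global_coupling = c(sleep_bout_h = 0.05,
                                                   insomnia = 0.06, dozing = -0.08,
                                                   phq2 = 0.06, cognition = 0.02),
                          rest_edge_coupling = NULL,
                          thickness_coupling = c(sleep_bout_h = 0.02, insomnia = 0,
                                                 dozing = -0.01, phq2 = -0.02,
                                                 cognition = 0.02),
                          covariate_leakage = 0,
                          voxel_noise_sd = 1, ar1 = 0.1, drift_amplitude = 1,
                          baseline_signal = 100,
                          rest_noise_sd = 0.1,
                          thickness_noise_sd = 0.1) {
  ph <- phenotype_names()
  stopifnot(is.matrix(phenotype_corr), dim(phenotype_corr) == c(5, 5))
  if (max(abs(phenotype_corr - t(phenotype_corr))) > 1e-10) {
    stop_sleepsig("invalid_argument", "phenotype_corr must be symmetric.")
  }
  if (max(abs(diag(phenotype_corr) - 1)) > 1e-10) {
    stop_sleepsig("invalid_argument", "phenotype_corr must have unit diagonal.")
  }
  ev <- eigen(phenotype_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop_sleepsig("invalid_argument",
                  sprintf("phenotype_corr is not positive definite (smallest eigenvalue %.3g).",
                          min(ev)))
  }
  if (is.null(latent_corr) &&
      isTRUE(all.equal(phenotype_corr, default_phenotype_corr(),
                       check.attributes = FALSE, tolerance = 1e-12)) &&
      identical(marginals, default_marginals())) {
    latent_corr <- default_latent_corr_values()
  }
  fill <- function(x) {
    if (is.matrix(x)) return(x)   # per-unit coupling matrices pass through
    out <- stats::setNames(numeric(5), ph)
    out[names(x)] <- x
    out
  }
  structure(
    list(
      phenotype_corr = phenotype_corr,
      latent_corr = latent_corr,
      marginals = marginals,
      task_coupling = fill(task_coupling),
      task_a0 = task_a0,
      rest_global_coupling = fill(rest_global_coupling),
      rest_edge_coupling = rest_edge_coupling,
      thickness_coupling = fill(thickness_coupling),
      covariate_leakage = covariate_leakage,
      voxel_noise_sd = voxel_noise_sd, ar1 = ar1,
      drift_amplitude = drift_amplitude, baseline_signal = baseline_signal,
      rest_noise_sd = rest_noise_sd, thickness_noise_sd = thickness_noise_sd
    ),
    class = "coupling_spec"
  )
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat("<coupling_spec>\n")
  cat("  phenotype correlation targets (off-diagonal):\n")
  tg <- x$phenotype_corr
  idx <- which(upper.tri(tg) & tg != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    cat(sprintf("    %s - %s: %.3f\n", rownames(tg)[idx[k, 1]],
                colnames(tg)[idx[k, 2]], tg[idx[k, 1], idx[k, 2]]))
  }
  cat("  task amplitude couplings: ",
      paste(sprintf("%s=%.2f", names(x$task_coupling), x$task_coupling),
            collapse = ", "), "\n", sep = "")
  cat("  rest global couplings:    ",
      paste(sprintf("%s=%.2f", names(x$rest_global_coupling), x$rest_global_coupling),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Calibrate latent Gaussian correlations against ordinal attenuation
#'
#' Discretizing latent Gaussian scores into ordinal scales attenuates
#' Pearson correlations, so the latent correlation matrix must exceed
#' the observed-scale targets. This routine iteratively adjusts the
#' latent matrix: at each sweep it simulates `n` latent draws, applies
#' the marginal transforms, measures the realized correlations, and
#' moves each latent entry by the remaining gap (projected back to
#' positive definite when needed).
#'
#' @param targets Target observed-scale 5x5 correlation matrix.
#' @param marginals Marginal descriptors ([default_marginals()]).
#' @param n Monte-Carlo draws per sweep.
#' @param sweeps Number of adjustment sweeps.
#' @param seed Integer seed.
#' @return Calibrated latent correlation matrix.
#' @export
calibrate_latent_corr <- function(targets = default_phenotype_corr(),
                                  marginals = default_marginals(),
                                  n = 2e5, sweeps = 10, seed = 1) {
  withr::local_seed(seed)
  ph <- rownames(targets) %||% phenotype_names()
  latent <- targets
  for (s in seq_len(sweeps)) {
    z <- rmvn(n, latent)
    obs <- z
    for (k in seq_along(ph)) obs[, k] <- apply_marginal(z[, k], marginals[[ph[k]]])
    realized <- stats::cor(obs)
    latent <- latent + (targets - realized)
    latent[latent > 0.99] <- 0.99
    latent[latent < -0.99] <- -0.99
    diag(latent) <- 1
    ev <- eigen(latent, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-6) latent <- make_pd(latent)
  }
  dimnames(latent) <- dimnames(targets)
  latent
}
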