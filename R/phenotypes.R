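#' Generate a synthetic phenotype and covariate table
#'
#' Draws a cohort of `n_subjects` from a Gaussian copula: latent
#' standard-normal scores with the calibrated latent correlation of
#' `coupling` are mapped through the marginal transforms of
#' [default_marginals()] (affine sleep hours, thresholded ordinals,
#' rounded count). Covariates are drawn independently of the phenotypes
#' unless `coupling$covariate_leakage` is non-zero, in which case a
#' linear age term leaks into every latent score before discretization.
#'
#' @param n_subjects Number of subjects.
#' @param coupling A [coupling_spec()].
#' @param seed Integer seed; the output table is byte-identical across
#'   runs with the same seed.
#' @return A tibble with `subject_id`, the five phenotypes
#'   ([phenotype_names()]), and covariates `age`, `sex`, `site`, `ses`,
#'   `education`, `ethnicity`, `accel_time_offset`, `head_motion`,
#'   `task_acc_mean`, `task_rt_mean`, `task_rt_sd`.
#' @export
#' @examples
#' ph <- generate_phenotypes(500, seed = 1)
generate_phenotypes <- function(n_subjects, coupling = coupling_spec(), seed = 1) {
  check_number(n_subjects, "n_subjects", min = 20)
  n_subjects <- as.integer(n_subjects)
  stopifnot(inherits(coupling, "coupling_spec"))
  latent_corr <- coupling$latent_corr
  if (is.null(latent_corr)) {
    latent_corr <- calibrate_latent_corr(coupling$phenotype_corr,
                                         coupling$marginals,
                                         n = 1e5, sweeps = 8,
                                         seed = stage_seed(seed, 99L))
  }
  withr::local_seed(seed)
  ph <- phenotype_names()
  z <- rmvn(n_subjects, latent_corr)

  # covariates, independent of the latent phenotype scores
  age <- round(stats::runif(n_subjects, 45, 80), 1)
  sex <- stats::rbinom(n_subjects, 1L, 0.5)
  site <- sample(c("siteA", "siteB", "siteC"), n_subjects, replace = TRUE,
                 prob = c(0.45, 0.35, 0.20))
  ses <- stats::rnorm(n_subjects, 0, 3)
  education <- sample(0:5, n_subjects, replace = TRUE,
                      prob = c(0.08, 0.15, 0.25, 0.22, 0.2, 0.1))
  ethnicity <- sample(c("groupA", "groupB", "groupC", "groupD"), n_subjects,
                      replace = TRUE, prob = c(0.88, 0.06, 0.04, 0.02))
  accel_time_offset <- round(stats::rnorm(n_subjects, 750, 350))
  head_motion <- round(stats::rlnorm(n_subjects, log(0.12), 0.4), 4)
  task_acc_mean <- round(stats::rbeta(n_subjects, 28, 3), 4)
  task_rt_mean <- round(stats::rnorm(n_subjects, 550, 80), 1)
  task_rt_sd <- round(pmax(20, stats::rnorm(n_subjects, 120, 30)), 1)

  if (coupling$covariate_leakage != 0) {
    z <- z + coupling$covariate_leakage * as.numeric(scale(age))
  }

  obs <- lapply(seq_along(ph), function(k) {
    apply_marginal(z[, k], coupling$marginals[[ph[k]]])
  })
  names(obs) <- ph
  obs$sleep_bout_h <- round(obs$sleep_bout_h, 3)

  tibble(
    subject_id = sprintf("S%06d", seq_len(n_subjects)),
    sleep_bout_h = obs$sleep_bout_h,
    insomnia = as.integer(obs$insomnia),
    dozing = as.integer(obs$dozing),
    phq2 = as.integer(obs$phq2),
    cognition = as.integer(obs$cognition),
    age = age, sex = sex, site = site, ses = ses,
    education = as.integer(education), ethnicity = ethnicity,
    accel_time_offset = accel_time_offset, head_motion = head_motion,
    task_acc_mean = task_acc_mean, task_rt_mean = task_rt_mean,
    task_rt_sd = task_rt_sd
  )
}

# standardized phenotype scores (z per SD), as a named matrix
standardize_phenotypes <- function(phenotypes) {
  ph <- phenotype_names()
  miss <- setdiff(ph, names(phenotypes))
  if (length(miss) > 0) {
    stop_sleepsig("schema",
                  paste0("phenotype table is missing column(s): ",
                         paste(miss, collapse = ", ")))
  }
  m <- as.matrix(phenotypes[ph])
  scale(m)
}
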