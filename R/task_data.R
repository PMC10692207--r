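#' Generate task fMRI voxel data with planted category signal
#'
#' For each subject s and region g, category blocks add a region-specific
#' multivariate pattern to the voxel time series with amplitude
#' `a_sg = max(0, a0_g + sum_k tau_k z_k(s))`, where `z_k` are the
#' standardized phenotypes and `tau` is `coupling$task_coupling`. Face
#' and shape patterns differ, so linear separability of the two classes
#' increases monotonically with the amplitude. The pattern is inserted
#' 5 volumes after stimulus onset to emulate hemodynamic delay (the
#' preprocessing shift compensates it). Noise is AR(1) per voxel plus a
#' slow sinusoidal drift on top of a constant baseline intensity.
#'
#' @param phenotypes Phenotype table from [generate_phenotypes()].
#' @param atlas Atlas from [generate_atlas()].
#' @param design A [task_design()].
#' @param coupling A [coupling_spec()].
#' @param n_voxels Voxels per region (default 24).
#' @param seed Integer seed.
#' @param hemodynamic_shift Volumes of delay planted in the data
#'   (default 5, matching the preprocessing default).
#' @return A tibble with columns `subject_id`, `region_id`, and a
#'   list-column `data` of voxel-by-time matrices; the design and the
#'   per-subject amplitude table are attached as attributes `design`
#'   and `amplitude`.
#' @export
generate_task_data <- function(phenotypes, atlas, design = task_design(),
                               coupling = coupling_spec(), n_voxels = 24,
                               seed = 1, hemodynamic_shift = 5) {
  check_atlas(atlas)
  validate_task_design(design)
  check_number(n_voxels, "n_voxels", min = 2)
  if (any(!is.finite(coupling$task_coupling))) {
    stop_sleepsig("invalid_argument", "task_coupling must be finite.")
  }
  withr::local_seed(seed)
  n_sub <- nrow(phenotypes)
  n_reg <- nrow(atlas)
  V <- as.integer(n_voxels)
  Tn <- design$n_volumes
  z <- standardize_phenotypes(phenotypes)
  z[is.nan(z)] <- 0
  amp_shift <- as.numeric(z %*% coupling$task_coupling)

  cats <- task_categories()
  b <- design$blocks
  # volumes occupied by each block, shifted by the hemodynamic delay
  sig_cols <- lapply(seq_len(nrow(b)), function(i) {
    v <- (b$onset[i] + hemodynamic_shift):(b$onset[i] + b$length[i] - 1 + hemodynamic_shift)
    v[v <= Tn]
  })

  out_subject <- rep(phenotypes$subject_id, each = n_reg)
  out_region <- rep(atlas$region_id, times = n_sub)
  data_list <- vector("list", n_sub * n_reg)

  # per-region baseline amplitudes, phenotype susceptibility profile
  # (shared across phenotypes, so planted signature maps are spatially
  # proportional), and category patterns
  a0 <- coupling$task_a0 * stats::runif(n_reg, 0.7, 1.3)
  susceptibility <- stats::runif(n_reg, 0.5, 1.5)
  patterns <- lapply(seq_len(n_reg), function(g) {
    class_pat <- list(
      shape = stats::rnorm(V),
      face = stats::rnorm(V)
    )
    pats <- lapply(seq_len(nrow(cats)), function(ci) {
      p <- class_pat[[cats$class[ci]]] + 0.4 * stats::rnorm(V)
      p / stats::sd(p)
    })
    names(pats) <- cats$category
    pats
  })

  sd_in <- coupling$voxel_noise_sd * sqrt(1 - coupling$ar1^2)
  tgrid <- seq_len(Tn)
  k <- 0L
  for (s in seq_len(n_sub)) {
    for (g in seq_len(n_reg)) {
      k <- k + 1L
      a_sg <- max(0, a0[g] + susceptibility[g] * amp_shift[s])
      # AR(1) voxel noise with stationary sd voxel_noise_sd
      eps <- matrix(stats::rnorm(V * Tn, sd = sd_in), V, Tn)
      noise <- t(apply(eps, 1, function(e) {
        as.numeric(stats::filter(e, coupling$ar1, method = "recursive"))
      }))
      # slow sinusoidal shift along the run (at most one cycle, so the
      # linear detrend has a real trend to remove), random phase
      phase <- stats::runif(V, 0, 2 * pi)
      cycles <- stats::runif(V, 0.2, 0.8)
      drift <- coupling$drift_amplitude *
        sin(outer(2 * pi * cycles, tgrid / Tn) + phase)
      x <- coupling$baseline_signal + noise + drift
      for (i in seq_len(nrow(b))) {
        x[, sig_cols[[i]]] <- x[, sig_cols[[i]]] +
          a_sg * patterns[[g]][[b$category[i]]]
      }
      data_list[[k]] <- x
    }
  }
  out <- tibble(subject_id = out_subject, region_id = out_region,
                data = data_list)
  attr(out, "design") <- design
  attr(out, "amplitude") <- tibble(subject_id = phenotypes$subject_id,
                                   amplitude_shift = amp_shift)
  attr(out, "susceptibility") <- susceptibility
  out
}
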