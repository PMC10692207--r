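#' Generate cortical thickness with planted phenotype effects
#'
#' Per subject and region: a 2.5 mm baseline, a fixed region offset,
#' a linear phenotype term `sum_k thickness_coupling_k * z_k(s)`, and
#' Gaussian residual noise.
#'
#' @param phenotypes Phenotype table.
#' @param atlas Atlas.
#' @param coupling A [coupling_spec()]; `thickness_coupling` may also
#'   be an R-by-5 matrix of region-specific slopes (mm per SD).
#' @param seed Integer seed.
#' @return Subjects-by-regions matrix (mm) with subject ids as
#'   rownames and region names `r<region_id>` as colnames.
#' @export
generate_thickness <- function(phenotypes, atlas, coupling = coupling_spec(),
                               seed = 1) {
  check_atlas(atlas)
  withr::local_seed(seed)
  n_sub <- nrow(phenotypes)
  R <- nrow(atlas)
  z <- standardize_phenotypes(phenotypes)
  z[is.nan(z)] <- 0
  tc <- coupling$thickness_coupling
  if (is.matrix(tc)) {
    if (nrow(tc) != R || ncol(tc) != 5) {
      stop_sleepsig("invalid_argument",
                    sprintf("thickness_coupling matrix must be %d x 5.", R))
    }
    effect <- z %*% t(tc)
  } else {
    # region susceptibility profile shared across phenotypes, so the
    # planted thickness signature maps are spatially proportional
    susceptibility <- stats::runif(R, 0.5, 1.5)
    effect <- outer(as.numeric(z %*% tc), susceptibility)
  }
  region_offset <- stats::rnorm(R, 0, 0.1)
  out <- 2.5 + matrix(region_offset, n_sub, R, byrow = TRUE) + effect +
    matrix(stats::rnorm(n_sub * R, 0, coupling$thickness_noise_sd), n_sub, R)
  dimnames(out) <- list(phenotypes$subject_id, paste0("r", atlas$region_id))
  out
}
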