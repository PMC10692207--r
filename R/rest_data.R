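#' Generate resting-state connectivity with planted phenotype effects
#'
#' Builds per-subject edge vectors on the Fisher-z scale: a fixed base
#' connectivity (higher within than between the seven networks, plus a
#' fixed random edge texture), a brain-wide shift
#' `sum_k rest_global_coupling_k * z_k(s)` applied uniformly to every
#' edge, optional per-edge couplings, and Gaussian edge noise. Values
#' are mapped back through `tanh`, so correlations stay in (-1, 1).
#' A 21-component (IC) edge set of length 210 is generated by the same
#' scheme for the edge-wise association models.
#'
#' @param phenotypes Phenotype table.
#' @param atlas Atlas (defines R and the network structure).
#' @param coupling A [coupling_spec()]; `rest_edge_coupling` may be an
#'   edges-by-5 matrix of per-edge slopes.
#' @param seed Integer seed.
#' @param n_ics Number of independent components (default 21, giving
#'   210 IC edges).
#' @return An object of class `rest_data`: list with `edges`
#'   (subjects-by-edges matrix of region-pair correlations, edge order
#'   as [edge_index()]), `ic_edges` (subjects-by-210), `edge_index`,
#'   `subject_id`, and `n_regions`.
#' @export
generate_rest_data <- function(phenotypes, atlas, coupling = coupling_spec(),
                               seed = 1, n_ics = 21) {
  check_atlas(atlas)
  if (any(!is.finite(coupling$rest_global_coupling))) {
    stop_sleepsig("invalid_argument", "rest_global_coupling must be finite.")
  }
  withr::local_seed(seed)
  n_sub <- nrow(phenotypes)
  R <- nrow(atlas)
  idx <- edge_index(R)
  E <- nrow(idx)
  z <- standardize_phenotypes(phenotypes)
  z[is.nan(z)] <- 0

  same_net <- atlas$network[idx$i] == atlas$network[idx$j]
  base <- ifelse(same_net, 0.25, 0.05) + stats::rnorm(E, 0, 0.05)
  global_shift <- as.numeric(z %*% coupling$rest_global_coupling)
  # edge susceptibility to the brain-wide shift (shared across
  # phenotypes, giving planted signature maps a common spatial profile)
  susceptibility <- stats::runif(E, 0.5, 1.5)

  zedges <- matrix(base, n_sub, E, byrow = TRUE) +
    outer(global_shift, susceptibility)
  if (!is.null(coupling$rest_edge_coupling)) {
    ec <- coupling$rest_edge_coupling
    if (!is.matrix(ec) || nrow(ec) != E || ncol(ec) != 5) {
      stop_sleepsig("invalid_argument",
                    sprintf("rest_edge_coupling must be a %d x 5 matrix.", E))
    }
    zedges <- zedges + z %*% t(ec)
  }
  zedges <- zedges + matrix(stats::rnorm(n_sub * E, 0, coupling$rest_noise_sd),
                            n_sub, E)

  ic_idx <- edge_index(n_ics)
  Eic <- nrow(ic_idx)
  ic_base <- stats::rnorm(Eic, 0.1, 0.08)
  ic_susceptibility <- stats::runif(Eic, 0.5, 1.5)
  ic_z <- matrix(ic_base, n_sub, Eic, byrow = TRUE) +
    outer(global_shift, ic_susceptibility) +
    matrix(stats::rnorm(n_sub * Eic, 0, coupling$rest_noise_sd), n_sub, Eic)

  structure(
    list(edges = tanh(zedges), ic_edges = tanh(ic_z), edge_index = idx,
         subject_id = phenotypes$subject_id, n_regions = R),
    class = "rest_data"
  )
}

#' @export
print.rest_data <- function(x, ...) {
  cat(sprintf("<rest_data> %d subjects, %d regions (%d edges), %d IC edges\n",
              length(x$subject_id), x$n_regions, ncol(x$edges), ncol(x$ic_edges)))
  invisible(x)
}
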