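#' Canonical seven-network labels
#'
#' The seven-network cortical grouping used to aggregate connectivity
#' (visual, somatomotor, dorsal attention, ventral attention, limbic,
#' frontoparietal, default mode).
#'
#' @return Character vector of length seven.
#' @export
network_names <- function() {
  c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
    "limbic", "frontoparietal", "default")
}

#' Generate a bilateral cortical atlas
#'
#' Builds a synthetic parcellation of `n_regions` bilaterally merged
#' regions. Each region carries a left and a right spherical centroid
#' (unit norm), mirror-symmetric in x, and a network label from the
#' seven-network grouping. The default of 180 regions matches a
#' bilaterally merged HCP-style cortical parcellation.
#'
#' @param n_regions Number of bilateral regions (>= 4). Default 180.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A tibble with columns `region_id`, `name`, `network`,
#'   `x_left`, `y_left`, `z_left`, `x_right`, `y_right`, `z_right`.
#'   Left centroids have negative x, right centroids are their mirror
#'   images (x negated).
#' @export
#' @examples
#' atlas <- generate_atlas(14, seed = 1)
generate_atlas <- function(n_regions = 180, seed = 1) {
  check_number(n_regions, "n_regions", min = 4)
  n_regions <- as.integer(n_regions)
  withr::local_seed(seed)
  nets <- network_names()
  # contiguous network blocks with sizes as even as the count allows
  sizes <- rep(n_regions %/% 7L, 7L)
  extra <- n_regions %% 7L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  network <- rep(nets, times = sizes)
  xyz <- matrix(stats::rnorm(3L * n_regions), n_regions, 3L)
  xyz <- xyz / sqrt(rowSums(xyz^2))
  # left hemisphere carries negative x; right is the mirror image
  xyz[, 1L] <- -abs(xyz[, 1L])
  tibble(
    region_id = seq_len(n_regions),
    name = sprintf("R%03d", seq_len(n_regions)),
    network = network,
    x_left = xyz[, 1L], y_left = xyz[, 2L], z_left = xyz[, 3L],
    x_right = -xyz[, 1L], y_right = xyz[, 2L], z_right = xyz[, 3L]
  )
}

check_atlas <- function(atlas) {
  req <- c("region_id", "network", "x_left", "y_left", "z_left",
           "x_right", "y_right", "z_right")
  miss <- setdiff(req, names(atlas))
  if (length(miss) > 0) {
    stop_sleepsig("atlas_incomplete",
                  paste0("atlas is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyNA(atlas$network) || any(!nzchar(atlas$network))) {
    stop_sleepsig("atlas_incomplete", "every region must carry a network label.")
  }
  invisible(atlas)
}
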