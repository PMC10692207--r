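#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# classed error helper; class is prefixed so callers can catch
# specific failure modes with expect_error(class = ...)
stop_sleepsig <- function(class, message, ...) {
  abort(message, class = paste0("sleepsig_error_", class), ...)
}

check_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop_sleepsig("invalid_argument",
                  sprintf("`%s` must be a single finite number >= %g.", name, min))
  }
  invisible(x)
}

#' Canonical phenotype names
#'
#' The five phenotypes modelled throughout the package, in canonical order:
#' accelerometer-derived duration of the longest sleep bout (hours),
#' self-reported insomnia frequency (0-3), self-reported daytime dozing
#' frequency (0-3), PHQ-2 depression score (0-6), and a symbol-digit
#' substitution cognition score (count of correct matches).
#'
#' @return Character vector of length five.
#' @export
phenotype_names <- function() {
  c("sleep_bout_h", "insomnia", "dozing", "phq2", "cognition")
}

#' Enumerate unique region pairs (edges)
#'
#' Edges are the strict lower triangle of a symmetric region-by-region
#' matrix, in row-major order: i ascending, and j ascending within i
#' (2-1, 3-1, 3-2, 4-1, ...). All edge vectors in the package use this
#' ordering.
#'
#' @param n_regions Number of regions R.
#' @return A tibble with columns `edge`, `i`, `j` and `R*(R-1)/2` rows.
#' @export
#' @examples
#' edge_index(4)
edge_index <- function(n_regions) {
  check_number(n_regions, "n_regions", min = 2)
  n_regions <- as.integer(n_regions)
  i <- rep.int(2:n_regions, times = seq_len(n_regions - 1L))
  j <- unlist(lapply(2:n_regions, function(k) seq_len(k - 1L)), use.names = FALSE)
  tibble(edge = seq_along(i), i = i, j = j)
}

#' Vectorize the lower triangle of a symmetric matrix
#'
#' @param m Symmetric numeric matrix.
#' @return Numeric vector in [edge_index()] order.
#' @export
matrix_to_edges <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  idx <- edge_index(nrow(m))
  m[cbind(idx$i, idx$j)]
}

#' Rebuild a symmetric matrix from its edge vector
#'
#' Inverse of [matrix_to_edges()].
#'
#' @param v Edge vector in [edge_index()] order.
#' @param diag Value placed on the diagonal (default 1).
#' @return Symmetric matrix.
#' @export
edges_to_matrix <- function(v, diag = 1) {
  e <- length(v)
  r <- (1 + sqrt(1 + 8 * e)) / 2
  if (abs(r - round(r)) > 1e-9) {
    stop_sleepsig("invalid_argument",
                  sprintf("edge vector length %d is not R*(R-1)/2 for integer R.", e))
  }
  r <- as.integer(round(r))
  m <- matrix(0, r, r)
  idx <- edge_index(r)
  m[cbind(idx$i, idx$j)] <- v
  m <- m + t(m)
  diag(m) <- diag
  m
}

# multivariate normal draws via Cholesky; correlation matrix input
rmvn <- function(n, corr) {
  ch <- tryCatch(chol(corr), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    stop_sleepsig("invalid_argument",
                  sprintf("correlation matrix is not positive definite (smallest eigenvalue %.3g).",
                          min(ev)))
  }
  z <- matrix(stats::rnorm(n * ncol(corr)), n, ncol(corr))
  z %*% ch
}

# nearest positive-definite projection by eigenvalue flooring, then
# rescaling to unit diagonal
make_pd <- function(m, floor = 1e-6) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  out
}

# derive a stage seed from a base seed, staying inside 32-bit range
stage_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}
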