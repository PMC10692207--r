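#' Partial correlation with covariate adjustment
#'
#' Residualizes `x` and `y` on the covariate design (plus intercept)
#' and reports the Pearson correlation of the residuals. The two-sided
#' p-value comes from the exact null of the Pearson coefficient,
#' `(1 + r) / 2 ~ Beta(n_eff / 2, n_eff / 2)` with
#' `n_eff = n - k - 2` (k covariate columns); the confidence interval
#' uses the Fisher z transform. The default 99% level corrects for
#' testing five phenotype pairs at the 0.05 level.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Numeric matrix/data frame of covariate columns
#'   (may be empty or `NULL`).
#' @param conf_level Confidence level (default 0.99).
#' @return One-row tibble: `r`, `n_eff`, `p`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' x <- rnorm(50); y <- x + rnorm(50)
#' partial_correlation(x, y, cbind(z = rnorm(50)))
partial_correlation <- function(x, y, covariates = NULL, conf_level = 0.99) {
  n <- length(x)
  if (length(y) != n) {
    stop_sleepsig("invalid_argument", "x and y must have equal length.")
  }
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  covariates <- as.matrix(covariates)
  k <- ncol(covariates)
  if (n <= k + 3) {
    stop_sleepsig("insufficient_sample",
                  "need n greater than the covariate count plus 3.")
  }
  Xi <- cbind(`(Intercept)` = 1, covariates)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qrx$pivot[(qrx$rank + 1):ncol(Xi)]]
    stop_sleepsig("singular_design",
                  paste0("covariate design is rank deficient; collinear column(s): ",
                         paste(bad, collapse = ", ")))
  }
  rx <- qr.resid(qrx, x)
  ry <- qr.resid(qrx, y)
  if (stats::sd(rx) < 1e-14 || stats::sd(ry) < 1e-14) {
    stop_sleepsig("undefined_correlation",
                  "a residual vector has zero variance; the partial correlation is undefined.")
  }
  r <- stats::cor(rx, ry)
  n_eff <- n - k - 2
  p <- beta_null_p(r, n_eff)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se_z <- 1 / sqrt(n - k - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble(r = r, n_eff = n_eff, p = p,
         ci_low = tanh(z - q * se_z), ci_high = tanh(z + q * se_z))
}

# two-sided p for Pearson r under independence: (1+r)/2 ~ Beta(m/2, m/2)
beta_null_p <- function(r, m) {
  f <- stats::pbeta((1 + r) / 2, m / 2, m / 2)
  min(1, 2 * min(f, 1 - f))
}

#' Pairwise partial correlations among the five phenotypes
#'
#' Computes [partial_correlation()] for every phenotype pair with the
#' phenotype-stage covariates (age, sex, site, ethnicity, socioeconomic
#' status, education; the accelerometry time offset is added only for
#' pairs involving `sleep_bout_h`). Complete cases are taken per pair.
#' A pair is flagged significant when its 99% confidence interval
#' excludes zero (alpha 0.05 over five phenotypes).
#'
#' @param phenotypes Phenotype/covariate table.
#' @param conf_level Confidence level (default 0.99).
#' @return An object of class `pheno_corr`: tibble with one row per
#'   unordered pair: `phenotype_a`, `phenotype_b`, `r`, `n_eff`, `p`,
#'   `ci_low`, `ci_high`, `significant`.
#' @export
pairwise_partial_correlations <- function(phenotypes, conf_level = 0.99) {
  ph <- phenotype_names()
  miss <- setdiff(ph, names(phenotypes))
  if (length(miss) > 0) {
    stop_sleepsig("schema",
                  paste0("phenotype table is missing column(s): ",
                         paste(miss, collapse = ", ")))
  }
  pairs <- utils::combn(ph, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    involves_sleep <- "sleep_bout_h" %in% c(a, b)
    covs <- covariate_set("pheno", if (involves_sleep) "sleep_bout_h")
    use <- stats::complete.cases(phenotypes[c(a, b, setdiff(covs, "sex:age"))])
    tab <- phenotypes[use, ]
    X <- build_covariates(tab, covs)
    res <- partial_correlation(as.numeric(tab[[a]]), as.numeric(tab[[b]]),
                               X, conf_level = conf_level)
    dplyr::bind_cols(tibble(phenotype_a = a, phenotype_b = b), res)
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  class(out) <- c("pheno_corr", class(out))
  out
}

#' Square matrix view of pairwise phenotype correlations
#'
#' @param x A `pheno_corr` tibble from
#'   [pairwise_partial_correlations()].
#' @return Symmetric 5x5 matrix of r values with `NA` diagonal.
#' @export
pheno_corr_matrix <- function(x) {
  ph <- phenotype_names()
  m <- matrix(NA_real_, 5, 5, dimnames = list(ph, ph))
  for (i in seq_len(nrow(x))) {
    m[x$phenotype_a[i], x$phenotype_b[i]] <- x$r[i]
    m[x$phenotype_b[i], x$phenotype_a[i]] <- x$r[i]
  }
  m
}
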