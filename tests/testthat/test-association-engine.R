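test_that("exact linear data recovers coefficients with zero residuals", {
  x <- 1:10
  fit <- fit_ols(2 * x + 1, cbind(x = x))
  expect_equal(unname(fit$beta["x"]), 2)
  expect_equal(unname(fit$beta["(Intercept)"]), 1)
  expect_lt(max(abs(fit$residuals)), 1e-12)
})

test_that("five-point regression matches the normal-equations oracle", {
  x <- 1:5
  y <- c(2, 4, 5, 4, 5)
  # closed form: slope = Sxy / Sxx
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(slope, 0.6)
  fit <- fit_ols(y, cbind(x = x))
  expect_equal(unname(fit$beta["x"]), slope, tolerance = 1e-12)
})

test_that("fit_ols agrees with the explicit normal-equations solution", {
  withr::with_seed(71, {
    X <- cbind(a = rnorm(80), b = rnorm(80), c = rnorm(80))
    y <- X %*% c(1, -2, 0.5) + rnorm(80)
  })
  fit <- fit_ols(y, X)
  Xi <- cbind(1, X)
  beta_ne <- solve(crossprod(Xi), crossprod(Xi, y))
  expect_lt(max(abs(fit$beta - beta_ne)), 1e-8)
  lmfit <- lm(y ~ X)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(lmfit)))),
               tolerance = 1e-8)
})

test_that("null p-values are uniform and multi-response matches single", {
  withr::with_seed(72, {
    X <- cbind(x = rnorm(50))
    Y <- matrix(rnorm(50 * 1000), 50, 1000)
  })
  multi <- sleepsig:::fit_ols_multi(Y, X)
  expect_gt(stats::ks.test(multi$p["x", ], "punif")$p.value, 0.01)
  single <- fit_ols(Y[, 17], X)
  expect_equal(multi$beta[, 17], single$beta, tolerance = 1e-12)
  expect_equal(multi$p[, 17], single$p, tolerance = 1e-12)
})

test_that("rank-deficient designs abort naming the collinear column", {
  x <- rnorm(30)
  expect_error(fit_ols(rnorm(30), cbind(a = x, b = 2 * x)),
               regexp = "collinear column",
               class = "sleepsig_error_singular_design")
})

test_that("BH adjustment matches the step-up definition", {
  # direct step-up oracle
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(1, adj)
    out
  }
  expect_equal(adjust_fdr_bh(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(adjust_fdr_bh(0.37), 0.37)
  expect_equal(adjust_fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  p <- withr::with_seed(73, runif(200)^2)
  expect_equal(adjust_fdr_bh(p), bh_oracle(p), tolerance = 1e-12)
  expect_error(adjust_fdr_bh(c(0.5, 1.2)),
               class = "sleepsig_error_invalid_argument")
})

test_that("Bonferroni adjustment caps at 1 and validates m", {
  expect_equal(adjust_bonferroni(0.01, 5), 0.05)
  expect_equal(adjust_bonferroni(0.5, 10), 1)
  p <- withr::with_seed(74, runif(50))
  loop <- vapply(p, function(pi) min(1, pi * 105), numeric(1))
  expect_equal(adjust_bonferroni(p, 105), loop)
  expect_error(adjust_bonferroni(0.1, 0),
               class = "sleepsig_error_invalid_argument")
})

test_that("coefficient normalization divides by the floored classification error", {
  ph <- generate_phenotypes(200, seed = 75)
  Y <- withr::with_seed(75, matrix(rnorm(200 * 2), 200, 2,
                                   dimnames = list(ph$subject_id, c("u1", "u2"))))
  acc <- tibble::tibble(unit = c("u1", "u2"), accuracy = c(0.6, 1.0))
  maps <- map_association(Y, ph, "phq2", modality = "task",
                          accuracy_by_unit = acc)
  expect_equal(maps$beta_normalized[maps$unit == "u1"],
               maps$beta[maps$unit == "u1"] / 0.4)
  expect_equal(maps$beta_normalized[maps$unit == "u2"],
               maps$beta[maps$unit == "u2"] / (1 / 120))
})

test_that("zero-coupling association maps have nominal false-positive rates", {
  ph <- generate_phenotypes(300, seed = 76)
  Y <- withr::with_seed(76, matrix(rnorm(300 * 400), 300, 400,
                                   dimnames = list(ph$subject_id, NULL)))
  maps <- map_association(Y, ph, "sleep_bout_h", modality = "task")
  expect_gt(mean(maps$p < 0.05), 0.03)
  expect_lt(mean(maps$p < 0.05), 0.07)
  expect_true(all(maps$p_adjusted >= maps$p))
})

test_that("planted couplings are recovered with near-nominal CI coverage", {
  cover <- withr::with_seed(77, vapply(seq_len(200), function(i) {
    x <- rnorm(100)
    y <- 0.3 * x + rnorm(100)
    fit <- fit_ols(y, cbind(x = x))
    half <- qt(0.975, fit$df_residual) * fit$se["x"]
    abs(fit$beta["x"] - 0.3) <= half
  }, logical(1)))
  expect_gt(mean(cover), 0.90)
  expect_lte(mean(cover), 0.995)
})
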