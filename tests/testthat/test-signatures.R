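test_that("signature correlations match the direct formula and edge cases", {
  a <- withr::with_seed(101, rnorm(180))
  b <- withr::with_seed(102, rnorm(180))
  r <- signature_correlation(a, b)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_lt(abs(r - r_direct), 1e-12)
  expect_equal(signature_correlation(a, a), 1)
  expect_equal(signature_correlation(a, -a), -1)
  expect_error(signature_correlation(a, rep(1, 180)),
               class = "sleepsig_error_undefined_correlation")
  expect_error(signature_correlation(a, b[1:10]),
               class = "sleepsig_error_invalid_argument")
})

test_that("parametric p equals the t-transform and a permutation oracle", {
  expect_equal(pearson_p_beta(0, 30), 1)
  for (r in c(0.1, 0.4, -0.55)) {
    for (n in c(20, 50)) {
      t_stat <- r * sqrt((n - 2) / (1 - r^2))
      p_t <- 2 * pt(-abs(t_stat), n - 2)
      expect_lt(abs(pearson_p_beta(r, n) - p_t), 1e-10)
    }
  }
  expect_error(pearson_p_beta(0.5, 3),
               class = "sleepsig_error_insufficient_sample")
  # permutation oracle on a 12-unit pair
  withr::with_seed(103, {
    a <- rnorm(12)
    b <- 0.6 * a + rnorm(12)
    r_obs <- cor(a, b)
    perm <- vapply(seq_len(10000), function(i) cor(a, sample(b)), numeric(1))
  })
  p_perm <- mean(abs(perm) >= abs(r_obs))
  p_beta <- pearson_p_beta(r_obs, 12)
  mc_err <- 3 * sqrt(p_beta * (1 - p_beta) / 10000)
  expect_lt(abs(p_perm - p_beta), mc_err + 0.01)
})

test_that("spin test gives p = 0 for identical smooth maps", {
  at <- generate_atlas(40, seed = 104)
  L <- as.matrix(at[, c("x_left", "y_left", "z_left")])
  f <- as.numeric(L %*% c(1, -2, 0.5)) + withr::with_seed(105, rnorm(40, 0, 0.1))
  st <- spin_test(f, f, at, n_perm = 300, seed = 106)
  expect_equal(st$p_spin, 0)
  expect_equal(st$r_obs, 1)
})

test_that("observed correlation is invariant to joint region relabeling", {
  at <- generate_atlas(30, seed = 107)
  f <- withr::with_seed(108, rnorm(30))
  g <- withr::with_seed(109, rnorm(30))
  perm <- withr::with_seed(110, sample.int(30))
  st1 <- spin_test(f, g, at, n_perm = 50, seed = 1)
  st2 <- spin_test(f[perm], g[perm], at[perm, ], n_perm = 50, seed = 1)
  expect_equal(st1$r_obs, st2$r_obs)
})

test_that("label-permutation fallback matches a plain permutation null", {
  at <- generate_atlas(25, seed = 111)
  f <- withr::with_seed(112, rnorm(25))
  g <- withr::with_seed(113, rnorm(25))
  st <- spin_test(f, g, at, n_perm = 500, seed = 114, method = "label")
  expect_gt(st$p_spin, 0.05)
  expect_lt(abs(st$p_spin - pearson_p_beta(cor(f, g), 25)), 0.25)
})

test_that("constant maps propagate an undefined-correlation error", {
  at <- generate_atlas(20, seed = 115)
  expect_error(spin_test(rep(1, 20), rnorm(20), at, n_perm = 10),
               class = "sleepsig_error_undefined_correlation")
  expect_error(spin_test(rnorm(10), rnorm(10), at),
               class = "sleepsig_error_atlas_incomplete")
})

test_that("stratification thresholds follow the stated boundary rules", {
  ph <- generate_phenotypes(200, seed = 116)
  ph$phq2[1] <- 3L
  ph$sleep_bout_h[2] <- 6.8
  s1 <- stratify_cohort(ph, "phq2")
  expect_equal(s1[1], "depressed")
  s2 <- stratify_cohort(ph, "sleep_bout_h")
  expect_equal(s2[2], "long_sleepers")
  expect_equal(sum(table(s2)), 200)
})

test_that("stratified signature tables cover both strata consistently", {
  at <- generate_atlas(8, seed = 117)
  ph <- generate_phenotypes(600, seed = 117)
  rd <- generate_rest_data(ph, at, seed = 118)
  out <- stratified_signatures(rd, ph, "sleep_bout_h")
  expect_setequal(unique(out$stratum), c("long_sleepers", "short_sleepers"))
  expect_equal(nrow(out), 20)   # 10 pairs x 2 strata
  expect_true(all(abs(out$r) <= 1))
  # a stratum too small for the model is a classed error
  expect_error(stratified_signatures(rd, ph, "sleep_bout_h", threshold = 12),
               class = "sleepsig_error_stratification")
})
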