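test_that("constant voxels give zero percent signal change", {
  d <- task_design()
  data <- matrix(100, nrow = 3, ncol = d$n_volumes)
  prep <- preprocess_run(data, d, seed = 1)
  expect_equal(max(abs(prep$samples)), 0)
  expect_equal(nrow(prep$samples), 60)
  expect_equal(as.vector(table(prep$class)), c(30, 30))
})

test_that("a pure linear trend is removed by detrending", {
  d <- task_design()
  data <- matrix(100 + seq_len(d$n_volumes), nrow = 1)
  prep <- preprocess_run(data, d, seed = 1)
  expect_lt(max(abs(prep$samples)), 1e-10)
})

test_that("higher-order detrending removes a quadratic shift", {
  d <- task_design()
  t <- seq_len(d$n_volumes)
  data <- matrix(100 + 0.05 * t + 0.002 * (t - mean(t))^2, nrow = 1)
  lin <- preprocess_run(data, d, seed = 1)
  quad <- preprocess_run(data, d, seed = 1, detrend_order = 2)
  expect_lt(max(abs(quad$samples)), 1e-10)
  expect_gt(max(abs(lin$samples)), 1e-4)
})

test_that("the label shift spans 3.675 s at the default TR", {
  d <- task_design()
  expect_equal(5 * d$tr_s, 3.675)
})

test_that("overflow and degenerate voxels raise classed errors", {
  d <- task_design(tail_volumes = 0)
  data <- matrix(rnorm(2 * d$n_volumes, mean = 100), nrow = 2)
  expect_error(preprocess_run(data, d, shift_volumes = 5),
               class = "sleepsig_error_design_overflow")
  d2 <- task_design()
  bad <- matrix(100, nrow = 2, ncol = d2$n_volumes)
  v <- withr::with_seed(1, rnorm(d2$n_volumes))
  bad[2, ] <- v - mean(v)   # run mean exactly zero
  expect_error(preprocess_run(bad, d2),
               regexp = "voxel 2",
               class = "sleepsig_error_degenerate_voxel")
})

test_that("linearly separable data decodes perfectly; folds are stratified", {
  s <- make_separable(gap = 6, seed = 3)
  res <- decode_region(s$samples, s$labels, seed = 1)
  expect_equal(res$accuracy, 1)
  expect_length(res$fold_accuracies, 6)
  expect_equal(res$n_samples, 60)
})

test_that("decoding accuracy is invariant to sample order", {
  s <- make_separable(gap = 0.8, seed = 4)
  r1 <- decode_region(s$samples, s$labels, seed = 9)
  perm <- withr::with_seed(5, sample.int(60))
  r2 <- decode_region(s$samples[perm, ], s$labels[perm], seed = 9)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
})

test_that("label-permuted decoding sits at chance", {
  s <- make_separable(gap = 2, seed = 6)
  acc <- vapply(seq_len(200), function(i) {
    lab <- withr::with_seed(1000 + i, sample(s$labels))
    decode_region(s$samples, lab, seed = i)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.02)
})

test_that("the built-in solver agrees with the libsvm reference", {
  skip_if_not_installed("e1071")
  s <- make_separable(seed = 7)
  expect_equal(decode_region(s$samples, s$labels, seed = 2)$accuracy,
               decode_region(s$samples, s$labels, seed = 2,
                             engine = "e1071")$accuracy)
  diffs <- vapply(1:20, function(i) {
    si <- make_separable(gap = runif(1), seed = 100 + i)
    a <- decode_region(si$samples, si$labels, seed = i)$accuracy
    b <- decode_region(si$samples, si$labels, seed = i,
                       engine = "e1071")$accuracy
    abs(a - b)
  }, numeric(1))
  expect_lt(mean(diffs), 0.03)
})

test_that("single-class input is rejected", {
  s <- make_separable(seed = 8)
  expect_error(decode_region(s$samples, rep("face", 60)),
               class = "sleepsig_error_invalid_labels")
  expect_error(univariate_contrast(s$samples, rep("face", 60)),
               class = "sleepsig_error_invalid_labels")
})

test_that("univariate contrast reflects planted offsets linearly", {
  s <- make_separable(gap = 0, seed = 9)
  expect_lt(abs(univariate_contrast(s$samples, s$labels)), 0.2)
  x <- s$samples
  x[s$labels == "face", ] <- x[s$labels == "face", ] + 1
  expect_equal(univariate_contrast(x, s$labels),
               univariate_contrast(s$samples, s$labels) + 1)
  contrasts <- vapply(c(0.5, 1, 1.5), function(a) {
    xi <- s$samples
    xi[s$labels == "face", ] <- xi[s$labels == "face", ] + a
    univariate_contrast(xi, s$labels)
  }, numeric(1))
  expect_equal(diff(contrasts), rep(0.5, 2), tolerance = 1e-10)
})

test_that("chance calibration holds for the zero-signal generator", {
  at <- generate_atlas(6, seed = 61)
  ph <- generate_phenotypes(25, seed = 61)
  cp0 <- coupling_spec(task_coupling = c(sleep_bout_h = 0), task_a0 = 0)
  td <- generate_task_data(ph, at, coupling = cp0, n_voxels = 16, seed = 62)
  dec <- decode_cohort(td, seed = 63)
  expect_gt(mean(dec$accuracy), 0.48)
  expect_lt(mean(dec$accuracy), 0.52)
})
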