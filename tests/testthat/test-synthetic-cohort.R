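test_that("atlas generation is deterministic, mirror-symmetric, unit-norm", {
  a1 <- generate_atlas(4, seed = 1)
  a2 <- generate_atlas(4, seed = 1)
  expect_identical(a1, a2)

  at <- generate_atlas(180, seed = 3)
  expect_equal(nrow(at), 180)
  expect_setequal(unique(at$network), network_names())
  expect_equal(at$region_id, 1:180)
  expect_equal(at$x_left, -at$x_right)
  expect_equal(at$y_left, at$y_right)
  norms_l <- sqrt(at$x_left^2 + at$y_left^2 + at$z_left^2)
  norms_r <- sqrt(at$x_right^2 + at$y_right^2 + at$z_right^2)
  expect_true(all(abs(norms_l - 1) < 1e-9))
  expect_true(all(abs(norms_r - 1) < 1e-9))
  expect_error(generate_atlas(3), class = "sleepsig_error_invalid_argument")
})

test_that("phenotype tables are deterministic with in-range ordinals", {
  p1 <- generate_phenotypes(300, seed = 5)
  p2 <- generate_phenotypes(300, seed = 5)
  expect_identical(p1, p2)
  expect_false(anyNA(p1))
  expect_true(all(p1$insomnia %in% 0:3))
  expect_true(all(p1$dozing %in% 0:3))
  expect_true(all(p1$phq2 %in% 0:6))
  expect_true(all(p1$cognition >= 0))
  expect_true(all(p1$sex %in% 0:1))
})

test_that("latent layer reproduces the requested correlations (Monte-Carlo oracle)", {
  lat <- default_phenotype_corr()
  z <- withr::with_seed(11, sleepsig:::rmvn(5000, lat))
  expect_lt(max(abs(cor(z) - lat)), 0.05)
})

test_that("identity coupling gives independent phenotypes", {
  cp <- coupling_spec(phenotype_corr = diag(5) + 0,
                      latent_corr = diag(5) + 0)
  # restore dimnames stripped by arithmetic
  ph <- phenotype_names()
  dimnames(cp$phenotype_corr) <- dimnames(cp$latent_corr) <- list(ph, ph)
  n <- 5000
  tab <- generate_phenotypes(n, cp, seed = 21)
  cm <- cor(as.matrix(tab[phenotype_names()]))
  expect_lt(max(abs(cm[upper.tri(cm)])), 3 / sqrt(n))
})

test_that("non-positive-definite targets are rejected naming the eigenvalue", {
  bad <- matrix(0.9, 5, 5)
  bad[1, 2] <- bad[2, 1] <- -0.9
  diag(bad) <- 1
  dimnames(bad) <- list(phenotype_names(), phenotype_names())
  expect_error(coupling_spec(phenotype_corr = bad),
               regexp = "eigenvalue",
               class = "sleepsig_error_invalid_argument")
})

test_that("realized partial correlations stay calibrated at large n", {
  ph <- generate_phenotypes(1e5, seed = 31)
  pc <- pairwise_partial_correlations(ph)
  targets <- default_phenotype_corr()
  for (i in seq_len(nrow(pc))) {
    tg <- targets[pc$phenotype_a[i], pc$phenotype_b[i]]
    expect_lt(abs(pc$r[i] - tg), 0.01)
  }
})

test_that("task data dimensions, determinism, and amplitude floor", {
  at <- generate_atlas(4, seed = 1)
  ph <- generate_phenotypes(20, seed = 1)
  d <- task_design()
  td1 <- generate_task_data(ph, at, d, n_voxels = 8, seed = 2)
  td2 <- generate_task_data(ph, at, d, n_voxels = 8, seed = 2)
  expect_identical(td1$data, td2$data)
  expect_equal(nrow(td1), 80)
  expect_true(all(vapply(td1$data, function(m) all(dim(m) == c(8, d$n_volumes)),
                         logical(1))))
  expect_true(all(vapply(td1$data, function(m) all(is.finite(m)), logical(1))))
})

test_that("decoding separability rises monotonically with planted amplitude", {
  at <- generate_atlas(4, seed = 7)
  ph <- generate_phenotypes(20, seed = 7)
  acc <- vapply(c(0, 0.5, 2), function(a) {
    cp <- coupling_spec(task_coupling = c(sleep_bout_h = 0), task_a0 = a)
    td <- generate_task_data(ph, at, coupling = cp, n_voxels = 12, seed = 8)
    mean(decode_cohort(td, seed = 9)$accuracy)
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
  expect_lt(abs(acc[1] - 0.5), 0.04)
  expect_gt(acc[3], 0.9)
})

test_that("rest data has the declared edge layout and clipped values", {
  at <- generate_atlas(10, seed = 1)
  ph <- generate_phenotypes(30, seed = 1)
  rd1 <- generate_rest_data(ph, at, seed = 4)
  rd2 <- generate_rest_data(ph, at, seed = 4)
  expect_identical(rd1$edges, rd2$edges)
  expect_equal(ncol(rd1$edges), 45)
  expect_equal(ncol(rd1$ic_edges), 210)
  expect_true(all(abs(rd1$edges) < 1))
  expect_identical(rd1$edge_index, edge_index(10))
})

test_that("positive global rest coupling yields a positive fitted association", {
  at <- generate_atlas(10, seed = 2)
  ph <- generate_phenotypes(500, seed = 2)
  cp <- coupling_spec(rest_global_coupling = c(phq2 = 0.1))
  rd <- generate_rest_data(ph, at, cp, seed = 3)
  gm <- vapply(seq_len(nrow(rd$edges)),
               function(i) mean(rd$edges[i, ]), numeric(1))
  names(gm) <- rd$subject_id
  fit <- global_association(gm, ph, "phq2", modality = "rest")
  expect_gt(fit$t, 2)
})

test_that("thickness output has correct dimensions and planted-region power", {
  at <- generate_atlas(10, seed = 5)
  ph <- generate_phenotypes(2000, seed = 5)
  tc <- matrix(0, 10, 5)
  tc[7, 4] <- 0.05   # phq2 effect on region 7 only, 0.5 x noise sd
  cp <- coupling_spec(thickness_coupling = tc)
  th <- generate_thickness(ph, at, cp, seed = 6)
  expect_equal(dim(th), c(2000, 10))
  maps <- map_association(th, ph, "phq2", modality = "anat")
  expect_equal(maps$unit[which.min(maps$p)], "r7")
  expect_lt(maps$p_adjusted[maps$unit == "r7"], 0.05)
  expect_true(mean(th) > 2.3 && mean(th) < 2.7)
})

test_that("zero-coupling thickness maps are null-calibrated", {
  at <- generate_atlas(20, seed = 8)
  ph <- generate_phenotypes(500, seed = 8)
  cp <- coupling_spec(thickness_coupling = c(sleep_bout_h = 0),
                      task_coupling = c(sleep_bout_h = 0),
                      rest_global_coupling = c(sleep_bout_h = 0))
  th <- generate_thickness(ph, at, cp, seed = 9)
  maps <- map_association_all(th, ph, modality = "anat")
  expect_lt(mean(maps$p < 0.05), 0.10)
  expect_equal(sum(maps$p_adjusted < 0.05 / 5), 0)
})
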