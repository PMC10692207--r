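test_that("global mean connectivity matches a double-loop oracle", {
  m <- withr::with_seed(121, {
    a <- matrix(rnorm(100), 10, 10)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    a
  })
  loop <- 0
  k <- 0
  for (i in 2:10) for (j in 1:(i - 1)) {
    loop <- loop + m[i, j]
    k <- k + 1
  }
  expect_lt(abs(global_mean_connectivity(m) - loop / k), 1e-12)
  const <- matrix(0.37, 6, 6)
  diag(const) <- 1
  expect_equal(global_mean_connectivity(const), 0.37)
  asym <- m
  asym[1, 2] <- asym[1, 2] + 1
  expect_error(global_mean_connectivity(asym),
               class = "sleepsig_error_invalid_matrix")
})

test_that("a 180-region parcellation averages 16,110 unique pairs", {
  expect_equal(nrow(edge_index(180)), 16110)
  m <- matrix(1, 180, 180)
  expect_length(matrix_to_edges(m), 16110)
})

test_that("network block means match brute-force enumeration and recompose", {
  at <- generate_atlas(21, seed = 122)
  m <- withr::with_seed(123, {
    a <- matrix(rnorm(21 * 21), 21, 21)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    a
  })
  nb <- network_block_means(m, at)
  expect_identical(unclass(nb), t(unclass(nb)))
  # brute force for one within and one between block
  nets <- at$network
  pick <- function(na, nb_) {
    vals <- c()
    for (i in 2:21) for (j in 1:(i - 1)) {
      if ((nets[i] == na && nets[j] == nb_) ||
          (nets[i] == nb_ && nets[j] == na)) {
        vals <- c(vals, m[i, j])
      }
    }
    mean(vals)
  }
  expect_lt(abs(nb["visual", "visual"] - pick("visual", "visual")), 1e-12)
  expect_lt(abs(nb["visual", "default"] - pick("visual", "default")), 1e-12)
  # pair-count-weighted blocks recompose the global mean exactly
  idx <- edge_index(21)
  counts <- table(paste(pmin(nets[idx$i], nets[idx$j]),
                        pmax(nets[idx$i], nets[idx$j])))
  total <- 0
  for (nm in names(counts)) {
    ab <- strsplit(nm, " ")[[1]]
    total <- total + nb[ab[1], ab[2]] * counts[[nm]]
  }
  expect_lt(abs(total / nrow(idx) - global_mean_connectivity(m)), 1e-12)
})

test_that("degenerate network cases reduce to single edges or the global mean", {
  at1 <- generate_atlas(6, seed = 124)
  at1$network <- "visual"
  m <- withr::with_seed(125, {
    a <- matrix(rnorm(36), 6, 6)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    a
  })
  nb1 <- network_block_means(m, at1)
  expect_equal(nb1["visual", "visual"], global_mean_connectivity(m))
  at2 <- generate_atlas(4, seed = 126)[1:2, ]
  at2$network <- c("visual", "default")
  m2 <- matrix(c(1, 0.42, 0.42, 1), 2, 2)
  nb2 <- network_block_means(m2, at2)
  expect_equal(nb2["visual", "default"], 0.42)
  at3 <- generate_atlas(6, seed = 124)
  at3$network[2] <- NA
  expect_error(network_block_means(m, at3),
               class = "sleepsig_error_atlas_incomplete")
})

test_that("task global connectivity is a relabeling-invariant pair mean", {
  ident <- matrix(1, 9, 9)
  expect_equal(task_global_connectivity(list(a = ident))[["a"]], 1)
  m <- withr::with_seed(127, {
    a <- matrix(rnorm(81), 9, 9)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    a
  })
  perm <- withr::with_seed(128, sample.int(9))
  expect_equal(task_global_connectivity(list(m))[[1]],
               task_global_connectivity(list(m[perm, perm]))[[1]])
})

test_that("CPM recovers a noiseless linear rule almost perfectly", {
  ph <- generate_phenotypes(600, seed = 131)
  E <- withr::with_seed(131, matrix(rnorm(600 * 60), 600, 60))
  E[, 1:5] <- 5 * E[, 1:5]
  rownames(E) <- ph$subject_id
  ph$cognition <- rowMeans(E[, 1:5])
  cpm <- cpm_fit_predict(E, ph, "cognition", covariates = character(0),
                         seed = 132)
  expect_gt(cpm$performance_r, 0.99)
  expect_equal(length(cpm$empty_folds), 0)
  g <- glance(cpm)
  expect_equal(g$n_folds, 10)
  expect_equal(nrow(tidy(cpm)), 600)
})

test_that("classic positive/negative-network features also recover the rule", {
  ph <- generate_phenotypes(600, seed = 139)
  E <- withr::with_seed(5139, matrix(rnorm(600 * 40), 600, 40))
  E[, 1:6] <- 5 * E[, 1:6]
  rownames(E) <- ph$subject_id
  ph$cognition <- rowMeans(E[, 1:3]) - rowMeans(E[, 4:6])
  cpm <- cpm_fit_predict(E, ph, "cognition", covariates = character(0),
                         seed = 140, feature = "posneg")
  expect_gt(cpm$performance_r, 0.95)
})

test_that("edge selection is strictly below the threshold", {
  ph <- generate_phenotypes(200, seed = 133)
  E <- withr::with_seed(133, matrix(rnorm(200 * 30), 200, 30))
  rownames(E) <- ph$subject_id
  seed <- 134
  n_folds <- 10
  cpm <- cpm_fit_predict(E, ph, "cognition", covariates = character(0),
                         sel_p = 0.2, n_folds = n_folds, seed = seed)
  # reproduce fold 1's training selection independently
  fold <- withr::with_seed(seed, rep_len(seq_len(n_folds), 200)[sample.int(200)])
  tr <- fold != 1
  y <- ph$cognition[tr]
  Er <- qr.resid(qr(matrix(1, 200, 1)), E)
  r <- as.numeric(cor(Er[tr, ], y))
  tt <- r * sqrt((sum(tr) - 2) / (1 - r^2))
  pv <- 2 * pt(-abs(tt), sum(tr) - 2)
  expect_identical(cpm$selected_edges[[1]], which(pv < 0.2))
  expect_identical(which(pv < 0.2), which(!(pv >= 0.2)))
})

test_that("empty selections fall back to the training mean", {
  ph <- generate_phenotypes(150, seed = 135)
  E <- withr::with_seed(4135, matrix(rnorm(150 * 20), 150, 20))
  rownames(E) <- ph$subject_id
  cpm <- cpm_fit_predict(E, ph, "phq2", covariates = character(0),
                         sel_p = 1e-12, seed = 136)
  expect_equal(length(cpm$empty_folds), 10)
  means_ok <- vapply(1:10, function(f) {
    te <- cpm$predictions$fold == f
    all(abs(cpm$predictions$predicted[te] -
              mean(ph$phq2[cpm$predictions$fold != f])) < 1e-12)
  }, logical(1))
  expect_true(all(means_ok))
})

test_that("within-fold residualization still solves the construction example", {
  ph <- generate_phenotypes(600, seed = 137)
  E <- withr::with_seed(137, matrix(rnorm(600 * 40), 600, 40))
  E[, 1:5] <- 5 * E[, 1:5]
  rownames(E) <- ph$subject_id
  ph$cognition <- rowMeans(E[, 1:5])
  cpm <- cpm_fit_predict(E, ph, "cognition", covariates = c("age", "sex"),
                         seed = 138, residualize = "fold")
  expect_gt(cpm$performance_r, 0.95)
})
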