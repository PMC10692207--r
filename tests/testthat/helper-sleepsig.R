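# fixtures built in code; everything deterministic under fixed seeds

# linearly separable two-class samples
make_separable <- function(n_per_class = 30, v = 10, gap = 4, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(n_per_class * v), n_per_class, v),
      matrix(rnorm(n_per_class * v), n_per_class, v)
    )
    x[seq_len(n_per_class), 1:3] <- x[seq_len(n_per_class), 1:3] + gap
    list(samples = x,
         labels = rep(c("face", "shape"), each = n_per_class))
  })
}

# voxel-by-time run with a planted face/shape pattern of amplitude a
make_run <- function(a = 0, v = 12, seed = 1, design = task_design()) {
  ph <- withr::with_seed(seed, generate_phenotypes(20, seed = seed))
  at <- generate_atlas(4, seed = seed)
  cp <- coupling_spec(task_coupling = c(sleep_bout_h = 0), task_a0 = a)
  td <- generate_task_data(ph[1, ], at[1, ], design, cp, n_voxels = v,
                           seed = seed)
  list(data = td$data[[1]], design = design)
}

# samples labelled with all seven categories, one mean pattern each
make_category_samples <- function(per_cat = 3, v = 8, scale = 1, seed = 1) {
  cats <- task_categories()$category
  withr::with_seed(seed, {
    pats <- matrix(rnorm(7 * v), 7, v)
    samples <- do.call(rbind, lapply(seq_along(cats), function(i) {
      matrix(rep(scale * pats[i, ], per_cat), per_cat, v, byrow = TRUE) +
        matrix(rnorm(per_cat * v, sd = 0.1), per_cat, v)
    }))
    list(samples = samples, category = rep(cats, each = per_cat))
  })
}
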