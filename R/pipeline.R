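#' Configure an end-to-end pipeline run
#'
#' @param n_subjects Cohort size (default 200).
#' @param n_regions Atlas size (default 20).
#' @param n_voxels Voxels per region (default 24).
#' @param coupling A [coupling_spec()].
#' @param design A [task_design()].
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param out_dir Output directory (`NULL` disables file output).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "phenocorr", "decode", "associate_task",
#'   "associate_anat", "restconn", "associate_rest", "signatures",
#'   "strata", "global", "cpm")`.
#' @param alpha Family significance level (default 0.05 over five
#'   phenotypes).
#' @param n_perm Spin-test permutations (default 1000).
#' @param sel_p,cpm_folds CPM selection threshold and folds.
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 200, n_regions = 20, n_voxels = 24,
                       coupling = coupling_spec(), design = task_design(),
                       seed = 1, out_dir = NULL,
                       stages = c("simulate", "phenocorr", "decode",
                                  "associate_task", "associate_anat",
                                  "restconn", "associate_rest", "signatures",
                                  "strata", "global", "cpm"),
                       alpha = 0.05, n_perm = 1000, sel_p = 0.01,
                       cpm_folds = 10) {
  structure(
    list(n_subjects = n_subjects, n_regions = n_regions,
         n_voxels = n_voxels, coupling = coupling, design = design,
         seed = seed, out_dir = out_dir, stages = stages, alpha = alpha,
         n_perm = n_perm, sel_p = sel_p, cpm_folds = cpm_folds),
    class = "run_config"
  )
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in order: cohort simulation, phenotype partial
#' correlations, per-region decoding, task/anatomical/resting
#' association maps, signature correlations with spin tests, stratified
#' re-analysis, global and network-wise mean connectivity, and CPM.
#' Stage outputs are returned in one result bundle and, when
#' `config$out_dir` is set, written as TSV files next to a JSON
#' manifest recording the seeds and configuration fingerprint.
#'
#' @param config A [run_config()].
#' @return A named list of stage results (class `sleepsig_run`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  res <- list(config = config, log = character(0), timings = numeric(0))
  need <- function(what, stage) {
    if (is.null(res[[what]])) {
      stop_sleepsig("dependency",
                    sprintf("stage '%s' needs '%s', which was not run.", stage, what))
    }
  }
  tick <- local({
    last <- proc.time()[[3]]
    function(stage) {
      now <- proc.time()[[3]]
      res$timings[stage] <<- round(now - last, 3)
      last <<- now
    }
  })
  seed <- config$seed

  if ("simulate" %in% st) {
    res$atlas <- generate_atlas(config$n_regions, seed = stage_seed(seed, 1L))
    res$phenotypes <- generate_phenotypes(config$n_subjects, config$coupling,
                                          seed = stage_seed(seed, 2L))
    res$task_data <- generate_task_data(res$phenotypes, res$atlas,
                                        config$design, config$coupling,
                                        n_voxels = config$n_voxels,
                                        seed = stage_seed(seed, 3L))
    res$rest <- generate_rest_data(res$phenotypes, res$atlas, config$coupling,
                                   seed = stage_seed(seed, 4L))
    res$thickness <- generate_thickness(res$phenotypes, res$atlas,
                                        config$coupling,
                                        seed = stage_seed(seed, 5L))
    tick("simulate")
  }
  if ("phenocorr" %in% st) {
    need("phenotypes", "phenocorr")
    res$pheno_corr <- pairwise_partial_correlations(res$phenotypes)
    tick("phenocorr")
  }
  if ("decode" %in% st) {
    need("task_data", "decode")
    res$decoding <- decode_cohort(res$task_data, config$design,
                                  seed = stage_seed(seed, 6L))
    tick("decode")
  }
  if ("associate_task" %in% st) {
    need("decoding", "associate_task")
    acc_wide <- tidyr::pivot_wider(res$decoding, id_cols = "subject_id",
                                   names_from = "region_id",
                                   values_from = "accuracy")
    Y <- as.matrix(acc_wide[-1])
    rownames(Y) <- acc_wide$subject_id
    acc_by_unit <- tibble(unit = colnames(Y), accuracy = colMeans(Y))
    res$task_maps <- map_association_all(Y, res$phenotypes, modality = "task",
                                         accuracy_by_unit = acc_by_unit)
    tick("associate_task")
  }
  if ("associate_anat" %in% st) {
    need("thickness", "associate_anat")
    Yt <- res$thickness
    res$anat_maps <- map_association_all(Yt, res$phenotypes, modality = "anat")
    tick("associate_anat")
  }
  if ("restconn" %in% st) {
    need("rest", "restconn")
  }
  if ("associate_rest" %in% st) {
    need("rest", "associate_rest")
    res$rest_maps <- dplyr::bind_rows(lapply(phenotype_names(), function(ph) {
      edge_associations(res$rest, res$phenotypes, ph)
    }))
    tick("associate_rest")
  }
  if ("signatures" %in% st) {
    need("task_maps", "signatures")
    need("rest_maps", "signatures")
    res$task_signatures <- signature_correlations(
      res$task_maps, atlas = res$atlas, n_perm = config$n_perm,
      seed = stage_seed(seed, 7L), alpha = config$alpha)
    res$rest_signatures <- signature_correlations(res$rest_maps,
                                                  alpha = config$alpha)
    if (!is.null(res$anat_maps)) {
      res$anat_signatures <- signature_correlations(
        res$anat_maps, atlas = res$atlas, n_perm = config$n_perm,
        seed = stage_seed(seed, 8L), alpha = config$alpha)
    }
    tick("signatures")
  }
  if ("strata" %in% st) {
    need("rest", "strata")
    # a stratum can be too small at modest n (depression prevalence is
    # a few percent); record the condition and carry on
    try_stratum <- function(variable) {
      tryCatch(stratified_signatures(res$rest, res$phenotypes, variable),
               sleepsig_error_stratification = function(e) {
                 res$log <<- c(res$log,
                               sprintf("strata(%s) skipped: %s", variable,
                                       conditionMessage(e)))
                 NULL
               })
    }
    res$strata_phq2 <- try_stratum("phq2")
    res$strata_sleep <- try_stratum("sleep_bout_h")
    tick("strata")
  }
  if ("global" %in% st) {
    need("rest", "global")
    rest_mats <- lapply(seq_along(res$rest$subject_id), function(i) {
      edges_to_matrix(res$rest$edges[i, ])
    })
    rest_global <- vapply(rest_mats, global_mean_connectivity, numeric(1))
    names(rest_global) <- res$rest$subject_id
    res$global_rest <- dplyr::bind_rows(lapply(phenotype_names(), function(ph) {
      global_association(rest_global, res$phenotypes, ph, modality = "rest")
    }))
    if (!is.null(res$task_data)) {
      repconn <- repconn_cohort(res$task_data, config$design,
                                seed = stage_seed(seed, 9L))
      task_global <- task_global_connectivity(repconn)
      res$global_task <- dplyr::bind_rows(lapply(phenotype_names(), function(ph) {
        global_association(task_global, res$phenotypes, ph, modality = "task")
      }))
      res$network_blocks_task <- network_block_means(
        Reduce(`+`, repconn) / length(repconn), res$atlas)
    }
    res$network_blocks_rest <- network_block_means(
      edges_to_matrix(colMeans(res$rest$edges)), res$atlas)
    tick("global")
  }
  if ("cpm" %in% st) {
    need("rest", "cpm")
    res$cpm <- lapply(stats::setNames(nm = phenotype_names()), function(ph) {
      cpm_fit_predict(res$rest, res$phenotypes, ph, sel_p = config$sel_p,
                      n_folds = config$cpm_folds,
                      seed = stage_seed(seed, 10L))
    })
    tick("cpm")
  }
  class(res) <- "sleepsig_run"
  if (!is.null(config$out_dir)) write_run(res, config$out_dir)
  res
}

# write a result bundle as TSV files plus a JSON manifest
write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  w <- function(x, name) {
    if (!is.null(x)) write_table_tsv(x, file.path(out_dir, name))
  }
  w(res$atlas, "atlas.tsv")
  w(res$phenotypes, "phenotypes.tsv")
  w(res$pheno_corr, "phenotype_correlations.tsv")
  w(res$decoding, "decoding.tsv")
  w(res$task_maps, "task_association_maps.tsv")
  w(res$anat_maps, "thickness_association_maps.tsv")
  w(res$rest_maps, "rest_association_maps.tsv")
  w(res$task_signatures, "task_signature_correlations.tsv")
  w(res$rest_signatures, "rest_signature_correlations.tsv")
  w(res$strata_phq2, "signatures_by_phq2.tsv")
  w(res$strata_sleep, "signatures_by_sleep.tsv")
  w(res$global_rest, "global_rest_associations.tsv")
  w(res$global_task, "global_task_associations.tsv")
  if (!is.null(res$rest)) {
    write_edges_tsv(res$rest$edges, file.path(out_dir, "rest_edges.tsv"),
                    subject_id = res$rest$subject_id,
                    index = res$rest$edge_index)
  }
  if (!is.null(res$cpm)) {
    cpm_tab <- dplyr::bind_rows(lapply(names(res$cpm), function(ph) {
      tibble(phenotype = ph, performance_r = res$cpm[[ph]]$performance_r,
             n_folds = res$cpm[[ph]]$n_folds,
             empty_folds = length(res$cpm[[ph]]$empty_folds))
    }))
    w(cpm_tab, "cpm_performance.tsv")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("sleepsig")),
    seed = cfg$seed,
    stage_seeds = stats::setNames(
      vapply(1:10, function(i) stage_seed(cfg$seed, i), integer(1)),
      c("atlas", "phenotypes", "task_data", "rest", "thickness", "decode",
        "spin_task", "spin_anat", "repconn", "cpm")),
    n_subjects = cfg$n_subjects, n_regions = cfg$n_regions,
    n_voxels = cfg$n_voxels, stages = cfg$stages,
    alpha = cfg$alpha, n_perm = cfg$n_perm, sel_p = cfg$sel_p,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    log = res$log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (length(res$timings) > 0) {
    write_table_tsv(tibble(stage = names(res$timings),
                           seconds = as.numeric(res$timings)),
                    file.path(out_dir, "stage_timings.tsv"))
  }
  invisible(out_dir)
}

#' @export
print.sleepsig_run <- function(x, ...) {
  parts <- setdiff(names(x), c("config", "log", "timings"))
  cat("<sleepsig_run> stages computed:", paste(parts, collapse = ", "), "\n")
  invisible(x)
}
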