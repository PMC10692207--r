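#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a CPM fit
#'
#' @param x A `sleepsig_cpm` object.
#' @param ... Unused.
#' @return Tibble of out-of-fold predictions (`subject_id`, `fold`,
#'   `predicted`, `observed`).
#' @export
tidy.sleepsig_cpm <- function(x, ...) {
  x$predictions
}

#' One-row summary of a CPM fit
#'
#' @param x A `sleepsig_cpm` object.
#' @param ... Unused.
#' @return Tibble with `performance_r`, `n_folds`, `sel_p`,
#'   `n_selected_median`, `n_empty_folds`.
#' @export
glance.sleepsig_cpm <- function(x, ...) {
  tibble(
    performance_r = x$performance_r,
    n_folds = x$n_folds,
    sel_p = x$sel_p,
    n_selected_median = stats::median(lengths(x$selected_edges)),
    n_empty_folds = length(x$empty_folds)
  )
}

#' Tidy a decoding result
#'
#' @param x A `decoding_result` object.
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @export
tidy.decoding_result <- function(x, ...) {
  tibble(fold = seq_along(x$fold_accuracies),
         accuracy = x$fold_accuracies)
}

#' One-row summary of a decoding result
#'
#' @param x A `decoding_result` object.
#' @param ... Unused.
#' @return Tibble with `accuracy`, `n_samples`, `n_folds`.
#' @export
glance.decoding_result <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_samples = x$n_samples,
         n_folds = x$n_folds)
}
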