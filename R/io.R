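#' Write and read the package's tabular files
#'
#' All tables are tab-separated text with a header row; numeric values
#' round-trip to at least 12 significant digits. Edge files carry the
#' declared lower-triangle order as explicit `i`, `j` columns
#' (`i > j`, row-major). Readers validate the schema and name the
#' offending line on malformed input.
#'
#' @param x Object to write (tibble, or matrix for
#'   [write_matrix_tsv()]).
#' @param path File path.
#' @name sleepsig_io
NULL

#' @rdname sleepsig_io
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname sleepsig_io
#' @param required Character vector of required column names.
#' @export
read_table_tsv <- function(path, required = NULL) {
  out <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    lazy = FALSE)
  )
  pr <- readr::problems(out)
  if (nrow(pr) > 0) {
    stop_sleepsig("parse",
                  sprintf("malformed row at line %d of %s: %s", pr$row[1] + 1L,
                          path, pr$expected[1]))
  }
  if (!is.null(required)) {
    miss <- setdiff(required, names(out))
    if (length(miss) > 0) {
      stop_sleepsig("schema",
                    paste0(path, " is missing column(s): ",
                           paste(miss, collapse = ", ")))
    }
  }
  out
}

#' @rdname sleepsig_io
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(is.matrix(x))
  df <- tibble::as_tibble(x, .name_repair = "minimal")
  names(df) <- colnames(x) %||% paste0("c", seq_len(ncol(x)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname sleepsig_io
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(read_table_tsv(path))
}

#' @rdname sleepsig_io
#' @param edges Subjects-by-edges matrix.
#' @param subject_id Subject identifiers (rownames used when `NULL`).
#' @param index Edge index tibble ([edge_index()]).
#' @export
write_edges_tsv <- function(edges, path, subject_id = NULL, index = NULL) {
  subject_id <- subject_id %||% rownames(edges)
  index <- index %||% edge_index((1 + sqrt(1 + 8 * ncol(edges))) / 2)
  long <- tibble(
    subject_id = rep(subject_id, each = nrow(index)),
    i = rep(index$i, times = nrow(edges)),
    j = rep(index$j, times = nrow(edges)),
    value = as.numeric(t(edges))
  )
  readr::write_tsv(long, path)
  invisible(path)
}

#' @rdname sleepsig_io
#' @export
read_edges_tsv <- function(path) {
  long <- read_table_tsv(path, required = c("subject_id", "i", "j", "value"))
  subjects <- unique(long$subject_id)
  idx <- dplyr::distinct(long[c("i", "j")])
  idx <- idx[order(idx$i, idx$j), ]
  key <- paste(long$i, long$j)
  ukey <- paste(idx$i, idx$j)
  out <- matrix(NA_real_, length(subjects), nrow(idx),
                dimnames = list(subjects, NULL))
  out[cbind(match(long$subject_id, subjects), match(key, ukey))] <- long$value
  out
}
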