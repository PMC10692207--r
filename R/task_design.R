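#' Stimulus categories of the face/shape matching task
#'
#' Seven stimulus categories: three shapes (circle, horizontal ellipse,
#' vertical ellipse) and four faces (male, female, angry, fearful), each
#' mapped to the binary class used by the decoder.
#'
#' @return A tibble with columns `category` and `class`.
#' @export
task_categories <- function() {
  tibble(
    category = c("circle", "h_ellipse", "v_ellipse",
                 "male_face", "female_face", "angry_face", "fearful_face"),
    class = c("shape", "shape", "shape", "face", "face", "face", "face")
  )
}

#' Define a block design for the face/shape task
#'
#' The default design has 10 blocks per class (20 in total, alternating
#' shape/face and cycling through the seven categories), 6 task volumes
#' per block averaged 2-at-a-time into 3 samples, and 4 rest volumes
#' between blocks. It therefore yields exactly 60 class-labelled
#' samples per subject, balanced 30 face / 30 shape, at a repetition
#' time of 0.735 s (so the 5-volume hemodynamic shift spans 3.675 s).
#'
#' @param n_blocks_per_class Blocks per class (default 10).
#' @param block_volumes Task volumes per block (default 6).
#' @param volumes_per_sample Consecutive volumes averaged into one
#'   sample (default 2; must divide `block_volumes`).
#' @param rest_volumes Rest volumes between blocks (default 4).
#' @param initial_rest Rest volumes before the first block (default 8).
#' @param tail_volumes Rest volumes appended after the last block so the
#'   hemodynamic shift stays in range (default 9).
#' @param tr_s Repetition time in seconds (default 0.735).
#' @return An object of class `task_design`: a list with `blocks` (a
#'   tibble with `block`, `onset`, `length`, `category`, `class`),
#'   `n_volumes`, `tr_s`, `volumes_per_sample`, and `n_samples`.
#' @export
#' @examples
#' d <- task_design()
#' d$n_samples # 60
task_design <- function(n_blocks_per_class = 10, block_volumes = 6,
                        volumes_per_sample = 2, rest_volumes = 4,
                        initial_rest = 8, tail_volumes = 9, tr_s = 0.735) {
  check_number(n_blocks_per_class, "n_blocks_per_class", min = 1)
  check_number(block_volumes, "block_volumes", min = 1)
  check_number(volumes_per_sample, "volumes_per_sample", min = 1)
  if (block_volumes %% volumes_per_sample != 0) {
    stop_sleepsig("invalid_argument",
                  "volumes_per_sample must divide block_volumes.")
  }
  cats <- task_categories()
  shape_cats <- cats$category[cats$class == "shape"]
  face_cats <- cats$category[cats$class == "face"]
  n_blocks <- 2L * as.integer(n_blocks_per_class)
  # alternate shape/face blocks, cycling the categories of each class
  class_seq <- rep(c("shape", "face"), n_blocks_per_class)
  category <- character(n_blocks)
  category[class_seq == "shape"] <-
    rep_len(shape_cats, n_blocks_per_class)
  category[class_seq == "face"] <-
    rep_len(face_cats, n_blocks_per_class)
  stride <- block_volumes + rest_volumes
  onset <- initial_rest + 1L + (seq_len(n_blocks) - 1L) * stride
  blocks <- tibble(
    block = seq_len(n_blocks),
    onset = as.integer(onset),
    length = as.integer(block_volumes),
    category = category,
    class = class_seq
  )
  n_volumes <- initial_rest + n_blocks * stride - rest_volumes + tail_volumes
  design <- structure(
    list(blocks = blocks, n_volumes = as.integer(n_volumes), tr_s = tr_s,
         volumes_per_sample = as.integer(volumes_per_sample),
         n_samples = as.integer(n_blocks * block_volumes / volumes_per_sample)),
    class = "task_design"
  )
  validate_task_design(design)
  design
}

validate_task_design <- function(design) {
  b <- design$blocks
  if (any(b$onset < 1) || any(b$onset + b$length - 1 > design$n_volumes)) {
    stop_sleepsig("invalid_argument", "blocks fall outside the run.")
  }
  ends <- b$onset + b$length - 1
  if (any(b$onset[-1] <= ends[-nrow(b)])) {
    stop_sleepsig("invalid_argument", "blocks overlap.")
  }
  if (length(unique(b$class)) < 2) {
    stop_sleepsig("invalid_argument", "both classes must be present.")
  }
  invisible(design)
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("<task_design> %d blocks, %d volumes (TR %.3f s), %d samples\n",
              nrow(x$blocks), x$n_volumes, x$tr_s, x$n_samples))
  invisible(x)
}
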