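#' @title CSV interfaces
#' @description
#' Plain-CSV schemas for the design table, trial sequences, response
#' tables and fit scores, with schema validation that names the missing
#' column on failure. Outcomes are stored as the display strings ("snow"
#' for A, "sun" for B); pattern codes are stored as zero-padded
#' 4-character strings. All round-trips are lossless.
#' @name wpt-io
NULL

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

# patterns like 0110 read back as integers without this
.read_csv <- function(path) {
  utils::read.csv(path, colClasses = c(pattern = "character"),
                  stringsAsFactors = FALSE)
}

#' Write / read a design table as CSV
#'
#' Columns: `pattern`, `n_outcome_A`, `n_outcome_B`.
#'
#' @param design A `wpt_design` table.
#' @param path File path.
#' @return `read_design_csv()` returns a `wpt_design` table.
#' @export
write_design_csv <- function(design, path) {
  design <- .assert_design(design)
  utils::write.csv(design[, c("pattern", "n_outcome_A", "n_outcome_B")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- .require_columns(.read_csv(path),
                         c("pattern", "n_outcome_A", "n_outcome_B"),
                         "design CSV")
  .assert_pattern(df$pattern)
  df$n_total <- df$n_outcome_A + df$n_outcome_B
  n_rep <- sum(df$n_total) / 100L
  attr(df, "n_repeats") <- if (n_rep == as.integer(n_rep))
    as.integer(n_rep) else NA_integer_
  class(df) <- c("wpt_design", "data.frame")
  df
}

#' Write / read a trial sequence as CSV
#'
#' Columns: `trial_index`, `pattern`, `pos_cue1`..`pos_cue4` (slot name
#' or empty), `feedback_outcome` (display string).
#'
#' @param sequence Sequence from [generate_sequence()].
#' @param path File path.
#' @return `read_trials_csv()` returns the sequence with outcomes as
#'   "A"/"B" codes.
#' @export
write_trials_csv <- function(sequence, path) {
  .require_columns(sequence, c("trial_index", "pattern", "feedback_outcome"),
                   "trial sequence")
  out <- sequence
  out$feedback_outcome <- outcome_display(out$feedback_outcome)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- .require_columns(.read_csv(path),
                         c("trial_index", "pattern", "feedback_outcome"),
                         "trials CSV")
  df$feedback_outcome <- unname(outcome_code(df$feedback_outcome))
  df
}

#' Write / read a response table as CSV
#'
#' Columns: `participant_id`, `trial_index`, `pattern`, `choice`
#' (display string), `phase` ("train"/"test"), `true_strategy` (empty
#' for observed data).
#'
#' @param responses Response rows (one or more participants).
#' @param path File path.
#' @return `read_responses_csv()` returns responses with "A"/"B" choice
#'   codes.
#' @export
write_responses_csv <- function(responses, path) {
  .require_columns(responses,
                   c("participant_id", "trial_index", "pattern", "choice",
                     "phase"),
                   "response table")
  out <- responses
  out$choice <- outcome_display(out$choice)
  if (is.null(out$true_strategy)) out$true_strategy <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses_csv
#' @export
read_responses_csv <- function(path) {
  df <- .require_columns(.read_csv(path),
                         c("participant_id", "trial_index", "pattern",
                           "choice", "phase"),
                         "responses CSV")
  df$choice <- unname(outcome_code(df$choice))
  if (!is.null(df$true_strategy))
    df$true_strategy[is.na(df$true_strategy)] <- ""
  df
}

#' Write fit scores / confusion matrix / profile matrix as CSV
#'
#' @param fits A `wpt_fits` table.
#' @param path File path.
#' @export
write_fit_scores_csv <- function(fits, path) {
  .require_columns(fits, c("participant_id", "window", "strategy", "score",
                           "under_criterion"), "fit-score table")
  utils::write.csv(fits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fit_scores_csv
#' @param mat Labelled matrix (confusion or profile matrix).
#' @export
write_matrix_csv <- function(mat, path) {
  utils::write.csv(data.frame(row = rownames(mat), mat,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
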