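# Trial-table readers and writers (tab-separated text).

trial_columns <- c("trial", "pi_t", "change", "category", "stimulus_deg",
                   "measurement_deg", "response")

#' Write a trial table to tab-separated text
#'
#' The on-disk schema has one row per trial and columns `trial`, `pi_t`,
#' `change`, `category` (A/B), `stimulus_deg`, `measurement_deg`,
#' `response` (covert: A/B choice; overt: criterion in degrees). Numeric
#' values are written with enough precision to round-trip.
#'
#' @param x a [simulate_session()] object or trial data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(x, path) {
  df <- if (inherits(x, "cl_session")) x$trials else x
  validate_trial_table(df)
  out <- df[, trial_columns]
  for (cn in c("pi_t", "stimulus_deg", "measurement_deg"))
    out[[cn]] <- formatC(out[[cn]], digits = 15, format = "g")
  if (is.numeric(out$response))
    out$response <- formatC(out$response, digits = 15, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trial table written by [write_trials()]
#'
#' @param path file path.
#' @return data.frame with the documented columns; the `response` column is
#'   numeric for overt sessions and "A"/"B" for covert sessions.
#' @export
read_trials <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(response = "character"))
  validate_trial_table(df)
  if (all(df$response %in% c("A", "B"))) df else {
    r <- suppressWarnings(as.numeric(df$response))
    if (anyNA(r))
      stop("validation error in column 'response': entries must all be ",
           "A/B choices or all numeric criteria", call. = FALSE)
    df$response <- r
    df
  }
}

validate_trial_table <- function(df) {
  stop_if_not(is.data.frame(df), "trial table must be a data.frame")
  miss <- setdiff(trial_columns, names(df))
  if (length(miss))
    stop("validation error: trial table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(df$category %in% c("A", "B")))
    stop("validation error in column 'category': labels must be 'A' or 'B'",
         call. = FALSE)
  for (cn in c("pi_t", "stimulus_deg", "measurement_deg"))
    if (!is.numeric(df[[cn]]) || anyNA(df[[cn]]))
      stop("validation error in column '", cn,
           "': must be numeric without missing values", call. = FALSE)
  if (anyNA(df$response))
    stop("validation error in column 'response': missing values", call. = FALSE)
  n <- nrow(df)
  lens <- vapply(df[trial_columns], length, integer(1))
  if (any(lens != n))
    stop("validation error: column length mismatch", call. = FALSE)
  invisible(df)
}
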