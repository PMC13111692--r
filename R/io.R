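# Reading and writing the package's delimited tabular interchange formats.
# Trial logs and displacement logs are plain CSV with ISO-8601 timestamps.

#' Read / write trial logs
#'
#' Trial logs are CSV files with header columns `individual_id`,
#' `timestamp` (ISO-8601), `trial_index`, `left_outcome`, `left_prob`,
#' `right_outcome`, `right_prob`, `choice`, `condition`, `domain`.
#' Missing `condition`/`domain` columns are re-derived from the lottery
#' fields on read.
#'
#' @param path File path.
#' @return `read_trial_log` returns the trial data.frame.
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("individual_id", "timestamp", "trial_index",
                       "left_outcome", "left_prob", "right_outcome",
                       "right_prob", "choice"), what = path)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%S")
  if (!all(c("condition", "domain") %in% names(df))) {
    cls <- classify_pairs(df)
    df$condition <- cls$condition
    df$domain <- cls$domain
  }
  validate_lottery(c(df$left_outcome, df$right_outcome),
                   c(df$left_prob, df$right_prob))
  df[order(df$individual_id, df$trial_index), , drop = FALSE]
}

#' @rdname read_trial_log
#' @param trials Trial data.frame to write.
#' @export
write_trial_log <- function(trials, path) {
  stopifnot_cols(trials, TRIAL_LOG_COLUMNS)
  out <- trials[, TRIAL_LOG_COLUMNS]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write displacement-event logs
#'
#' Event logs are CSV files with columns `timestamp` (ISO-8601),
#' `winner_id`, `loser_id`.
#'
#' @param path File path.
#' @return `read_event_log` returns the event data.frame.
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("timestamp", "winner_id", "loser_id"), what = path)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%S")
  df[order(df$timestamp), , drop = FALSE]
}

#' @rdname read_event_log
#' @param events Event data.frame to write.
#' @export
write_event_log <- function(events, path) {
  stopifnot_cols(events, c("timestamp", "winner_id", "loser_id"))
  out <- events[, c("timestamp", "winner_id", "loser_id")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise PT parameters to / from flat key-value records
#'
#' @param params A [pt_params()] vector.
#' @return `pt_params_to_list` returns a named list with exactly the
#'   seven canonical fields (JSON-compatible); `pt_params_from_list` is
#'   its inverse.
#' @export
pt_params_to_list <- function(params) {
  params <- as_pt_params(params)
  as.list(stats::setNames(as.numeric(params[PT_PARAM_NAMES]),
                          PT_PARAM_NAMES))
}

#' @rdname pt_params_to_list
#' @param x Named list or vector with the seven parameter fields.
#' @export
pt_params_from_list <- function(x) {
  as_pt_params(x)
}
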