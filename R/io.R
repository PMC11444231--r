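# Artifact IO: participant tables as CSV, event logs as JSON Lines, session
# configurations as JSON. Readers validate structure and report the first
# offending line rather than silently dropping data.

PARTICIPANT_COLUMNS <- c("participant_id", "condition", "seed", "n_doses",
                         "n_correct_on_time", "n_correct_off_time",
                         "n_wrong_code", "n_missed", "adherence_rate",
                         "relapsed", "relapse_round", "final_score", "earnings")

#' Write a participant table to CSV
#'
#' @param records Data frame from [run_experiment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(records, path) {
  stopifnot(all(PARTICIPANT_COLUMNS %in% names(records)))
  utils::write.csv(records[PARTICIPANT_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a participant table from CSV
#'
#' Validates the header and per-line field counts; a truncated or malformed
#' file raises an error naming the first bad line.
#'
#' @param path CSV path written by [write_participants()].
#' @return Data frame of participant records.
#' @export
read_participants <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("empty participant file: ", path, call. = FALSE)
  # per-line structural check: balanced quotes and a constant field count
  # (a truncated line cannot hide inside a quote-spanning record)
  n_quotes <- vapply(gregexpr('"', lines, fixed = TRUE),
                     function(m) sum(m > 0), integer(1))
  n_fields <- nchar(gsub("[^,]", "", gsub('"[^"]*"', "q", lines))) + 1L
  bad <- which(n_quotes %% 2 == 1 | n_fields != n_fields[1])
  if (length(bad) > 0)
    stop(sprintf("malformed participant CSV %s: line %d is truncated or has %d fields, expected %d",
                 path, bad[1], n_fields[bad[1]], n_fields[1]), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PARTICIPANT_COLUMNS, names(tab))
  if (length(missing) > 0)
    stop("participant CSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  tab$relapse_round <- as.integer(tab$relapse_round)
  tab
}

#' Write an event log as JSON Lines
#'
#' One JSON object per line; each row of the event data frame becomes one
#' event object.
#'
#' @param events Event data frame from [run_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(events)))
    writeLines(jsonlite::toJSON(as.list(events[r, , drop = FALSE]),
                                auto_unbox = TRUE, na = "null", digits = NA),
               con)
  invisible(path)
}

#' Read a JSON Lines event log
#'
#' @param path Path written by [write_event_log()].
#' @return Event data frame; malformed lines raise an error with the line
#'   number.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop(sprintf(
                      "malformed event log %s: line %d: %s",
                      path, i, conditionMessage(e)), call. = FALSE))
    obj[vapply(obj, is.null, logical(1))] <- NA
    as.data.frame(obj, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a session configuration as JSON
#'
#' @param config A [session_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a session configuration from JSON
#'
#' Unknown keys are rejected; the result is re-validated through
#' [session_config()].
#'
#' @param path JSON path written by [write_config()].
#' @return A `session_config`.
#' @export
read_config <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("malformed config ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  known <- names(formals(session_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(session_config, obj)
}
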