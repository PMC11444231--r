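# The five trial arms. Incentive and reminder leave illness mechanics
# untouched (only earnings / agent context change); commitment changes
# nothing in the environment at all (it is an agent-side construct); the
# elongated-symptoms arm doubles the number of correct entries required for
# the screen to stay clear.

#' Names of the trial arms
#' @export
condition_names <- c("control", "incentive", "reminder", "commitment", "elongated")

#' Build a condition specification
#'
#' @param name One of [condition_names].
#' @param base_config The control-arm [session_config()] the overrides apply to.
#' @param reminder_duration_s How long the reminder popup stays visible
#'   (reminder arm; "a few seconds" in the protocol, default 3).
#' @return A `condition_spec`: the arm name, the partial config overrides,
#'   the reminder duration, and the agent context flags
#'   (`incentive_active`, `reminder_shown`, `commitment_signed`).
#' @examples
#' make_condition("elongated")$env_overrides  # clear_after_doses doubled
#' @export
make_condition <- function(name, base_config = session_config(),
                           reminder_duration_s = 3) {
  if (!is.character(name) || length(name) != 1 || !(name %in% condition_names))
    stop(sprintf("unknown condition '%s'; valid conditions: %s",
                 as.character(name)[1], paste(condition_names, collapse = ", ")),
         call. = FALSE)
  overrides <- switch(name,
    control    = list(),
    incentive  = list(),
    reminder   = list(),
    commitment = list(),
    elongated  = list(clear_after_doses = 2L * base_config$clear_after_doses)
  )
  flags <- list(
    incentive_active  = identical(name, "incentive"),
    reminder_shown    = identical(name, "reminder"),
    commitment_signed = identical(name, "commitment")
  )
  structure(
    list(name = name, env_overrides = overrides,
         reminder_duration_s = reminder_duration_s,
         agent_context_flags = flags),
    class = "condition_spec"
  )
}

#' Apply a condition's overrides to a session configuration
#'
#' @param spec A `condition_spec` from [make_condition()].
#' @param config The base [session_config()].
#' @return A validated `session_config` with the arm's overrides and label.
#' @export
apply_condition <- function(spec, config) {
  stopifnot(inherits(spec, "condition_spec"), inherits(config, "session_config"))
  for (k in names(spec$env_overrides)) config[[k]] <- spec$env_overrides[[k]]
  config$condition <- spec$name
  validate_session_config(config)
}

#' Reminder popup schedule
#'
#' One popup per scheduled dose, shown for `reminder_duration_s` seconds
#' starting at the scheduled time. Non-reminder arms get an empty schedule.
#'
#' @param spec A `condition_spec`.
#' @param config A [session_config()].
#' @return A data frame with columns `onset_t`, `offset_t` (seconds).
#' @export
reminder_schedule <- function(spec, config) {
  stopifnot(inherits(spec, "condition_spec"))
  if (!identical(spec$name, "reminder"))
    return(data.frame(onset_t = numeric(0), offset_t = numeric(0)))
  onset <- schedule_doses(config)
  data.frame(onset_t = onset, offset_t = onset + spec$reminder_duration_s)
}
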