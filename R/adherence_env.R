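# The illness/treatment overlay on top of the game: a 14-minute-30-second
# session in which a code must be entered once per minute (14 doses, the
# analog of a 7-day twice-daily antibiotic course). The screen starts fully
# blurred (symptom onset), clears linearly with correct entries, and stays
# clear after enough doses; once cleared, missing a dose risks relapse with
# a hazard that starts at 2% and doubles per consecutive miss, each relapse
# re-blurring the screen by 25%.

DOSE_OUTCOMES <- c("CORRECT_ON_TIME", "CORRECT_OFF_TIME", "WRONG_CODE", "MISSED")

#' Session configuration
#'
#' All illness/treatment parameters of one session. Defaults are the control
#' arm of the laboratory task: 870 s session, 14 doses a minute apart,
#' full initial blur clearing after 7 correct entries, 2% relapse hazard
#' doubling per consecutive miss and capped at one relapse, Rs 80 show-up
#' fee, Rs 500 earnings cap, Rs 5 on-time bonus in the incentive arm.
#'
#' @param session_duration_s Session length in seconds.
#' @param dose_interval_s Seconds between scheduled doses.
#' @param n_doses Number of scheduled doses.
#' @param on_time_window_s Half-width (s) of the on-time window around each
#'   scheduled dose; entries farther out are "correct, wrong time".
#' @param initial_blur Starting blur fraction in \[0, 1\].
#' @param clear_after_doses Correct entries needed for the screen to stay
#'   clear (7 control; 14 in the elongated-symptoms arm).
#' @param relapse_base_p Relapse probability on the first post-clearance miss.
#' @param relapse_multiplier Hazard multiplier per additional consecutive miss.
#' @param relapse_blur_increment Blur added by one relapse.
#' @param max_relapses Maximum relapse events per session.
#' @param show_up_fee Baseline earnings in rupees.
#' @param earnings_cap Maximum earnings in rupees.
#' @param incentive_bonus Rupees per on-time entry (paid in the incentive arm).
#' @param score_rupee_rate Rupees credited per game point (default 420 rupees
#'   per 20,000 points).
#' @param code The medication code participants must type.
#' @param condition Condition label (see [condition_names]).
#' @return A validated `session_config` list.
#' @examples
#' cfg <- session_config()
#' schedule_doses(cfg)
#' @export
session_config <- function(session_duration_s = 870,
                           dose_interval_s = 60,
                           n_doses = 14,
                           on_time_window_s = 15,
                           initial_blur = 1.0,
                           clear_after_doses = 7,
                           relapse_base_p = 0.02,
                           relapse_multiplier = 2,
                           relapse_blur_increment = 0.25,
                           max_relapses = 1,
                           show_up_fee = 80,
                           earnings_cap = 500,
                           incentive_bonus = 5,
                           score_rupee_rate = 420 / 20000,
                           code = "1879",
                           condition = "control") {
  cfg <- structure(
    list(session_duration_s = as.numeric(session_duration_s),
         dose_interval_s = as.numeric(dose_interval_s),
         n_doses = as.integer(n_doses),
         on_time_window_s = as.numeric(on_time_window_s),
         initial_blur = as.numeric(initial_blur),
         clear_after_doses = as.integer(clear_after_doses),
         relapse_base_p = as.numeric(relapse_base_p),
         relapse_multiplier = as.numeric(relapse_multiplier),
         relapse_blur_increment = as.numeric(relapse_blur_increment),
         max_relapses = as.integer(max_relapses),
         show_up_fee = as.numeric(show_up_fee),
         earnings_cap = as.numeric(earnings_cap),
         incentive_bonus = as.numeric(incentive_bonus),
         score_rupee_rate = as.numeric(score_rupee_rate),
         code = as.character(code),
         condition = as.character(condition)),
    class = "session_config"
  )
  validate_session_config(cfg)
}

validate_session_config <- function(cfg) {
  with(cfg, {
    if (n_doses < 1) stop("n_doses must be >= 1", call. = FALSE)
    if (n_doses * dose_interval_s > session_duration_s)
      stop("n_doses * dose_interval_s exceeds session_duration_s", call. = FALSE)
    if (relapse_base_p < 0 || relapse_base_p > 1)
      stop("relapse_base_p must be in [0, 1]", call. = FALSE)
    if (relapse_multiplier < 1) stop("relapse_multiplier must be >= 1", call. = FALSE)
    if (initial_blur < 0 || initial_blur > 1)
      stop("initial_blur must be in [0, 1]", call. = FALSE)
    if (on_time_window_s <= 0 || on_time_window_s > dose_interval_s / 2)
      stop("on_time_window_s must be in (0, dose_interval_s / 2]", call. = FALSE)
    if (show_up_fee > earnings_cap) stop("show_up_fee exceeds earnings_cap", call. = FALSE)
    if (clear_after_doses < 1) stop("clear_after_doses must be >= 1", call. = FALSE)
  })
  cfg
}

#' Initial environment state for a session
#'
#' @param config A [session_config()].
#' @return An `env_state`: elapsed time, blur, pill counter, consecutive-miss
#'   counter, relapse bookkeeping, earnings (starting at the show-up fee) and
#'   cumulative game score.
#' @export
env_state <- function(config) {
  structure(
    list(t = 0,
         blur = config$initial_blur,
         doses_taken = 0L,          # pill counter: correct entries, on or off time
         n_on_time = 0L,
         consecutive_misses = 0L,
         relapsed = FALSE,
         relapse_round = NA_integer_,
         relapse_count = 0L,
         symptoms_cleared = FALSE,
         codes_effective = TRUE,
         earnings = config$show_up_fee,
         cumulative_game_score = 0,
         closed_windows = logical(config$n_doses),
         last_relapse_triggered = FALSE),
    class = "env_state"
  )
}

#' Scheduled dose times
#'
#' @param config A [session_config()].
#' @return Numeric vector `dose_interval_s * (1:n_doses)` in seconds.
#' @export
schedule_doses <- function(config) {
  stopifnot(inherits(config, "session_config"))
  validate_session_config(config)
  config$dose_interval_s * seq_len(config$n_doses)
}

#' Classify one code entry
#'
#' @param config A [session_config()].
#' @param dose_index Dose window index in `1:n_doses`.
#' @param entry_t Entry time in seconds, or `NA` if no entry was made.
#' @param entered_code The typed code, or `NA`.
#' @return One of `"CORRECT_ON_TIME"` (code matches, within
#'   `on_time_window_s` of schedule), `"CORRECT_OFF_TIME"`, `"WRONG_CODE"`,
#'   `"MISSED"`.
#' @export
classify_entry <- function(config, dose_index, entry_t = NA, entered_code = NA) {
  stopifnot(dose_index >= 1, dose_index <= config$n_doses)
  if (is.na(entry_t) || is.na(entered_code)) return("MISSED")
  if (!identical(as.character(entered_code), config$code)) return("WRONG_CODE")
  scheduled <- config$dose_interval_s * dose_index
  if (abs(entry_t - scheduled) <= config$on_time_window_s) "CORRECT_ON_TIME"
  else "CORRECT_OFF_TIME"
}

#' Relapse hazard after m consecutive misses
#'
#' Active only once symptoms have cleared: the first miss carries
#' `relapse_base_p` (2%), and the hazard multiplies by `relapse_multiplier`
#' (doubles) per further consecutive miss, capped at 1.
#'
#' @param config A [session_config()].
#' @param m Number of consecutive misses since clearance (>= 1).
#' @return Probability `min(1, relapse_base_p * relapse_multiplier^(m - 1))`.
#' @examples
#' cfg <- session_config()
#' sapply(1:7, relapse_hazard, config = cfg)  # 0.02 0.04 ... 1
#' @export
relapse_hazard <- function(config, m) {
  if (any(m < 1)) stop("m must be >= 1: no miss, no hazard", call. = FALSE)
  pmin(1, config$relapse_base_p * config$relapse_multiplier^(m - 1))
}

#' Blur level after a correct entry
#'
#' Before clearance, blur falls linearly with the pill counter:
#' `initial_blur * (1 - doses_taken / clear_after_doses)`, reaching 0 (and
#' permanent clearance) at `clear_after_doses` correct entries. After a
#' relapse has re-blurred a cleared screen, each further correct entry
#' removes the same per-dose decrement.
#'
#' @param state An `env_state` whose pill counter was just incremented.
#' @param config A [session_config()].
#' @return The state with `blur` (and possibly `symptoms_cleared`) updated.
#' @export
update_blur <- function(state, config) {
  step <- config$initial_blur / config$clear_after_doses
  if (!state$symptoms_cleared) {
    state$blur <- max(0, config$initial_blur *
                        (1 - state$doses_taken / config$clear_after_doses))
    if (state$doses_taken >= config$clear_after_doses) {
      state$blur <- 0
      state$symptoms_cleared <- TRUE
    }
  } else {
    state$blur <- max(0, state$blur - step)
  }
  state
}

#' Close one dose window and update the environment
#'
#' Applies the consequences of the window's outcome: an on-time correct entry
#' resets the consecutive-miss counter, advances the pill counter and clears
#' blur one step; an off-time correct entry also advances the pill counter
#' and clears blur, but (like a miss or wrong code) counts against the
#' relapse process once symptoms have cleared. Post-clearance misses draw a
#' Bernoulli relapse with [relapse_hazard()]; a relapse adds
#' `relapse_blur_increment` to blur (clamped to 1) and records the round;
#' further relapses are suppressed once `max_relapses` is reached. Before
#' clearance there is no relapse draw and the miss counter does not move.
#' After all `n_doses` windows close, codes become ineffective.
#'
#' @param state An `env_state`.
#' @param config A [session_config()].
#' @param dose_index Window index; closing a window twice is an error.
#' @param outcome One of the four dose outcomes (see [classify_entry()]).
#' @return The updated `env_state`; `last_relapse_triggered` flags whether
#'   this window's draw caused a relapse.
#' @export
close_dose_window <- function(state, config, dose_index, outcome) {
  stopifnot(inherits(state, "env_state"))
  outcome <- match.arg(outcome, DOSE_OUTCOMES)
  if (dose_index < 1 || dose_index > config$n_doses)
    stop(sprintf("dose_index %d outside 1..%d: windows are capped at n_doses",
                 dose_index, config$n_doses), call. = FALSE)
  if (state$closed_windows[dose_index])
    stop(sprintf("dose window %d already closed", dose_index), call. = FALSE)
  if (!state$codes_effective)
    stop("codes are no longer effective: all dose windows closed", call. = FALSE)

  state$last_relapse_triggered <- FALSE
  if (outcome == "CORRECT_ON_TIME") {
    state$consecutive_misses <- 0L
    state$doses_taken <- state$doses_taken + 1L
    state$n_on_time <- state$n_on_time + 1L
    state <- update_blur(state, config)
  } else {
    if (outcome == "CORRECT_OFF_TIME") {
      # a pill was taken, just off schedule: counts for blur, not adherence
      state$doses_taken <- state$doses_taken + 1L
      state <- update_blur(state, config)
    }
    if (state$symptoms_cleared) {
      state$consecutive_misses <- state$consecutive_misses + 1L
      if (state$relapse_count < config$max_relapses) {
        h <- relapse_hazard(config, state$consecutive_misses)
        if (stats::runif(1) < h) {
          state$blur <- min(1, state$blur + config$relapse_blur_increment)
          state$relapsed <- TRUE
          state$relapse_round <- as.integer(dose_index)
          state$relapse_count <- state$relapse_count + 1L
          state$last_relapse_triggered <- TRUE
        }
      }
    }
  }
  state$closed_windows[dose_index] <- TRUE
  if (all(state$closed_windows)) state$codes_effective <- FALSE
  state
}

#' Recompute session earnings
#'
#' Earnings are the Rs 80 show-up fee, plus the game score converted at
#' `score_rupee_rate`, plus (incentive arm only) Rs 5 per on-time entry,
#' capped at Rs 500.
#'
#' @param state An `env_state`.
#' @param config A [session_config()].
#' @return The state with `earnings` updated.
#' @export
apply_earnings <- function(state, config) {
  e <- config$show_up_fee + config$score_rupee_rate * state$cumulative_game_score
  if (identical(config$condition, "incentive"))
    e <- e + config$incentive_bonus * state$n_on_time
  state$earnings <- min(config$earnings_cap, e)
  state
}
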