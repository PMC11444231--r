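# The experiment harness: runs one 870 s session (game segments + 14 dose
# windows) for one agent, and whole multi-arm experiments with
# counter-based per-participant random substreams so every output bit is a
# function of (plan, master seed).

#' Experiment plan
#'
#' Per-arm sample sizes and the master seed. Defaults are the trial's arm
#' sizes: 104 control, 106 incentive, 97 reminder, 102 commitment device,
#' 100 elongated symptoms — 509 participants in total.
#'
#' @param n_per_arm Named integer vector of sample sizes; names must be a
#'   subset of [condition_names].
#' @param master_seed Integer master seed.
#' @return An `experiment_plan`.
#' @export
experiment_plan <- function(n_per_arm = c(control = 104L, incentive = 106L,
                                          reminder = 97L, commitment = 102L,
                                          elongated = 100L),
                            master_seed = 20151201L) {
  if (is.null(names(n_per_arm)) || !all(names(n_per_arm) %in% condition_names))
    stop("n_per_arm must be named with conditions from condition_names",
         call. = FALSE)
  if (any(n_per_arm < 0)) stop("sample sizes must be >= 0", call. = FALSE)
  structure(list(n_per_arm = n_per_arm,
                 master_seed = as.integer(master_seed)),
            class = "experiment_plan")
}

#' Run one participant session
#'
#' Simulates the 870 s session: game-score accrual between dose windows at
#' the current blur level, one agent decision per scheduled dose, entry
#' classification, window closure (miss counting, relapse draws), and final
#' earnings. All randomness comes from `seed`; identical inputs give
#' byte-identical outputs.
#'
#' Game accrual modes: `"abstract"` (default) draws points from the agent's
#' rate model [accrue_score()] once per constant-blur segment; `"engine"`
#' plays the actual 2048 engine one move per second with probability
#' `1 - blur_impairment * blur`, restarting finished boards and summing
#' scores across plays; `"none"` skips the game entirely (fast path for
#' calibration, where only adherence matters).
#'
#' @param config A [session_config()] (before condition overrides).
#' @param condition A `condition_spec` from [make_condition()], or an arm
#'   name.
#' @param params An [agent_params()].
#' @param seed Integer seed for this participant's substream.
#' @param game One of `"abstract"`, `"engine"`, `"none"`.
#' @param keep_events Return the per-dose event trace?
#' @return List with `record` (one-row data frame: id fields, outcome
#'   counts, adherence rate in percent, relapse round, final score,
#'   earnings) and `events` (data frame of dose events, or `NULL`).
#' @examples
#' s <- run_session(session_config(), make_condition("control"),
#'                  agent_params(), seed = 7)
#' s$record$adherence_rate
#' @export
run_session <- function(config, condition, params, seed,
                        game = c("abstract", "engine", "none"),
                        keep_events = TRUE) {
  game <- match.arg(game)
  if (is.character(condition)) condition <- make_condition(condition, config)
  stopifnot(inherits(condition, "condition_spec"),
            inherits(params, "agent_params"))
  cfg <- apply_condition(condition, config)
  flags <- condition$agent_context_flags

  with_seed(seed, {
    state <- env_state(cfg)
    sched <- schedule_doses(cfg)
    gstate <- if (game == "engine") new_game() else NULL
    half <- cfg$dose_interval_s / 2
    events <- vector("list", cfg$n_doses)
    seg_start <- 0

    for (i in seq_len(cfg$n_doses)) {
      state <- accrue_segment(state, params, sched[i] - seg_start, game, gstate)
      if (game == "engine" && !is.null(attr(state, "gstate"))) {
        gstate <- attr(state, "gstate")
        attr(state, "gstate") <- NULL
      }
      seg_start <- sched[i]

      ctx <- list(symptoms_cleared = state$symptoms_cleared,
                  reminder_shown = flags$reminder_shown,
                  incentive_active = flags$incentive_active,
                  commitment_signed = flags$commitment_signed)
      act <- decide_dose(params, ctx)
      if (act$attempt) {
        # jitter truncated to the dose's open half-interval around schedule
        off <- min(max(act$entry_offset_s, -half), half - 1)
        entry_t <- min(max(sched[i] + off, 0), cfg$session_duration_s)
        entered <- if (act$code_correct) cfg$code else paste0("x", cfg$code)
      } else {
        entry_t <- NA_real_
        entered <- NA_character_
      }
      outcome <- classify_entry(cfg, i, entry_t, entered)
      state <- close_dose_window(state, cfg, i, outcome)
      events[[i]] <- data.frame(
        event = "dose", dose_index = i, scheduled_t = sched[i],
        entry_t = entry_t, entered_code = entered, outcome = outcome,
        blur_after = state$blur,
        relapse_triggered = state$last_relapse_triggered,
        stringsAsFactors = FALSE)
    }
    state <- accrue_segment(state, params, cfg$session_duration_s - seg_start,
                            game, if (game == "engine") gstate else NULL)
    state$t <- cfg$session_duration_s
    state <- apply_earnings(state, cfg)

    n_out <- table(factor(vapply(events, function(e) e$outcome, character(1)),
                          levels = DOSE_OUTCOMES))
    record <- data.frame(
      condition = condition$name,
      seed = as.integer(seed),
      n_doses = cfg$n_doses,
      n_correct_on_time = as.integer(n_out[["CORRECT_ON_TIME"]]),
      n_correct_off_time = as.integer(n_out[["CORRECT_OFF_TIME"]]),
      n_wrong_code = as.integer(n_out[["WRONG_CODE"]]),
      n_missed = as.integer(n_out[["MISSED"]]),
      adherence_rate = 100 * n_out[["CORRECT_ON_TIME"]] / cfg$n_doses,
      relapsed = state$relapsed,
      relapse_round = state$relapse_round,
      final_score = state$cumulative_game_score,
      earnings = state$earnings,
      stringsAsFactors = FALSE)
    list(record = record,
         events = if (keep_events) do.call(rbind, events) else NULL)
  })
}

# Accrue game score over one constant-blur segment. In engine mode the
# game state rides along as an attribute.
accrue_segment <- function(state, params, dt, game, gstate) {
  if (dt <= 0 || game == "none") return(state)
  if (game == "abstract") {
    state$cumulative_game_score <-
      state$cumulative_game_score + accrue_score(params, state$blur, dt)
    return(state)
  }
  # engine mode: one move attempt per second, success rate impaired by blur
  p_move <- max(0, 1 - params$blur_impairment * state$blur)
  banked <- 0
  for (s in seq_len(floor(dt))) {
    if (stats::runif(1) >= p_move) next
    if (gstate$over) {
      banked <- banked + gstate$score
      gstate <- restart_if_over(gstate)
    }
    dirs <- legal_moves(gstate)
    if (length(dirs) > 0)
      gstate <- apply_move(gstate, dirs[sample.int(length(dirs), 1L)])
  }
  state$cumulative_game_score <-
    state$cumulative_game_score + banked + gstate$score
  gstate$score <- 0L  # banked into the session total
  attr(state, "gstate") <- gstate
  state
}

#' Run a multi-arm experiment
#'
#' Runs every arm of the plan at its sample size. Each participant gets a
#' seed derived from the master seed and a fixed per-arm counter block via
#' [derive_seed()], so records are independent across participants and
#' changing one arm's size never changes another participant's draws.
#'
#' @param plan An [experiment_plan()].
#' @param config Base (control) [session_config()].
#' @param params An [agent_params()] used for every agent.
#' @param game Game accrual mode passed to [run_session()].
#' @param keep_events Collect per-participant event traces?
#' @return A data frame of participant records (one row each) with a
#'   `consort` attribute (assigned = analyzed accounting per arm) and, when
#'   `keep_events`, an `events` attribute (named list of event data frames).
#' @export
run_experiment <- function(plan = experiment_plan(),
                           config = session_config(),
                           params = agent_params(),
                           game = c("abstract", "engine", "none"),
                           keep_events = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  game <- match.arg(game)
  arms <- names(plan$n_per_arm)
  records <- list()
  events <- list()
  for (a in seq_along(arms)) {
    arm <- arms[a]
    spec <- make_condition(arm, base_config = config)
    block <- (match(arm, condition_names) - 1L) * 1e6  # fixed counter block per arm
    for (i in seq_len(plan$n_per_arm[[arm]])) {
      sd_i <- derive_seed(plan$master_seed, block + i)
      out <- run_session(config, spec, params, seed = sd_i, game = game,
                         keep_events = keep_events)
      pid <- sprintf("%s-%03d", arm, i)
      rec <- cbind(data.frame(participant_id = pid, stringsAsFactors = FALSE),
                   out$record)
      records[[length(records) + 1L]] <- rec
      if (keep_events) events[[pid]] <- out$events
    }
  }
  tab <- do.call(rbind, records)
  rownames(tab) <- NULL
  consort <- data.frame(condition = arms,
                        assigned = as.integer(plan$n_per_arm),
                        analyzed = as.integer(table(factor(tab$condition,
                                                           levels = arms))))
  attr(tab, "consort") <- consort
  if (keep_events) attr(tab, "events") <- events
  tab
}

#' CONSORT-style accounting of an experiment
#'
#' @param records Output of [run_experiment()].
#' @return Data frame with `condition`, `assigned`, `analyzed`.
#' @export
consort_table <- function(records) {
  ct <- attr(records, "consort")
  if (is.null(ct)) stop("records carry no consort accounting", call. = FALSE)
  ct
}
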