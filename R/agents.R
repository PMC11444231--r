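# Synthetic participants. The laboratory task was run on humans; these
# agents are a deliberately minimal stochastic stand-in that reproduces the
# qualitative drivers of nonadherence reported for real patients —
# forgetting doses, lapsing once symptoms disappear, responding to reminders
# and incentives, and occasionally entering codes late or wrong. Attendance
# is an independent per-dose Bernoulli draw whose probability is shaped by
# context; timing jitter is Gaussian; wrong codes are a fixed error rate.
#
# Default parameters ship pre-calibrated (see calibrate()) so the control
# arm's mean adherence sits at the 44% level observed in the human control
# group, and the reminder arm near 67%. They are documentation of a
# plausible world, not claims of behavioral truth.

#' Behavioral parameters of a synthetic participant
#'
#' @param p_attend Probability of attempting a dose while symptomatic.
#'   Default calibrated so the control arm's mean adherence is ~44%.
#' @param symptom_free_mult Multiplier in \[0, 1\] on `p_attend` once
#'   symptoms have cleared (the "I feel fine" lapse).
#' @param reminder_compliance Fraction `r` of the remaining attendance gap
#'   closed when a reminder is shown: `p <- p + r (1 - p)`. Default chosen
#'   so the reminder arm's mean adherence is ~67%.
#' @param incentive_sensitivity Fraction `g` closed when the on-time bonus
#'   is active, same functional form.
#' @param commitment_boost Fraction `k` closed after signing the commitment
#'   sticker; default 0 (the arm had a null effect on humans).
#' @param timing_sd_s SD in seconds of the Gaussian entry-time jitter.
#' @param p_wrong_code Probability an attempted entry uses a wrong code.
#' @param skill Expected game points per second at zero blur.
#' @param blur_impairment Fraction of the score rate lost at full blur:
#'   rate multiplier is `1 - blur_impairment * blur`.
#' @return A validated `agent_params` list.
#' @examples
#' agent_params()
#' @export
agent_params <- function(p_attend = 0.6875,
                         symptom_free_mult = 0.5,
                         reminder_compliance = 0.82,
                         incentive_sensitivity = 0.25,
                         commitment_boost = 0,
                         timing_sd_s = 12.4,
                         p_wrong_code = 0.07,
                         skill = 20,
                         blur_impairment = 0.9) {
  p <- structure(
    list(p_attend = p_attend, symptom_free_mult = symptom_free_mult,
         reminder_compliance = reminder_compliance,
         incentive_sensitivity = incentive_sensitivity,
         commitment_boost = commitment_boost,
         timing_sd_s = timing_sd_s, p_wrong_code = p_wrong_code,
         skill = skill, blur_impairment = blur_impairment),
    class = "agent_params"
  )
  fracs <- c("p_attend", "symptom_free_mult", "reminder_compliance",
             "incentive_sensitivity", "commitment_boost", "p_wrong_code",
             "blur_impairment")
  for (f in fracs)
    if (p[[f]] < 0 || p[[f]] > 1)
      stop(sprintf("%s must be in [0, 1]", f), call. = FALSE)
  if (p$timing_sd_s < 0) stop("timing_sd_s must be >= 0", call. = FALSE)
  if (p$skill < 0) stop("skill must be >= 0", call. = FALSE)
  p
}

#' Dose-attendance probability in context
#'
#' Base probability `p_attend`, multiplied by `symptom_free_mult` once
#' symptoms have cleared, then boosted toward 1 by each active cue:
#' `p <- p + x (1 - p)` for reminder compliance `r`, incentive sensitivity
#' `g`, and commitment boost `k`.
#'
#' @param params An [agent_params()].
#' @param context List with logicals `symptoms_cleared`, `reminder_shown`,
#'   `incentive_active`, `commitment_signed` (missing entries count FALSE).
#' @return Probability in \[0, 1\].
#' @export
attend_probability <- function(params, context = list()) {
  flag <- function(nm) isTRUE(context[[nm]])
  p <- params$p_attend * (if (flag("symptoms_cleared")) params$symptom_free_mult else 1)
  if (flag("reminder_shown"))    p <- p + params$reminder_compliance * (1 - p)
  if (flag("incentive_active"))  p <- p + params$incentive_sensitivity * (1 - p)
  if (flag("commitment_signed")) p <- p + params$commitment_boost * (1 - p)
  min(1, max(0, p))
}

#' Draw one dose decision
#'
#' Attendance is Bernoulli([attend_probability()]); if attending, the entry
#' offset is Normal(0, `timing_sd_s`) rounded to whole seconds, and the code
#' is correct with probability `1 - p_wrong_code`.
#'
#' @inheritParams attend_probability
#' @param seed Optional seed.
#' @return List `attempt` (logical), `entry_offset_s` (integer, only when
#'   attempting), `code_correct` (logical, only when attempting).
#' @export
decide_dose <- function(params, context = list(), seed = NULL) {
  with_seed(seed, {
    if (stats::runif(1) >= attend_probability(params, context))
      return(list(attempt = FALSE, entry_offset_s = NA_integer_,
                  code_correct = NA))
    list(attempt = TRUE,
         entry_offset_s = as.integer(round(stats::rnorm(1, 0, params$timing_sd_s))),
         code_correct = stats::runif(1) >= params$p_wrong_code)
  })
}

#' Game points accrued over an interval
#'
#' Expected points are `skill * (1 - blur_impairment * blur) * dt`, floored
#' at zero; the draw is the stochastically-rounded expectation.
#'
#' @param params An [agent_params()].
#' @param blur Blur fraction in \[0, 1\].
#' @param dt Interval length in seconds (> 0).
#' @param seed Optional seed.
#' @return Non-negative integer points.
#' @export
accrue_score <- function(params, blur, dt, seed = NULL) {
  stopifnot(dt > 0)
  mu <- max(0, params$skill * (1 - params$blur_impairment * blur) * dt)
  with_seed(seed, {
    lo <- floor(mu)
    as.integer(lo + (stats::runif(1) < mu - lo))
  })
}

#' Calibrate the attendance probability to a target control-arm adherence
#'
#' Bisection search on `p_attend` (all other parameters fixed) against the
#' simulated control-arm mean adherence, using common random numbers across
#' candidate values so the objective is monotone in `p_attend`. The target is
#' a percentage (the human control arm sat at 44%).
#'
#' @param target_mean_adherence Target mean adherence in percent, in (0, 100);
#'   0 is allowed and returns `p_attend = 0` immediately.
#' @param params Starting [agent_params()]; only `p_attend` is searched.
#' @param config Control-arm [session_config()].
#' @param n_sims Simulated participants per objective evaluation (>= 100).
#' @param seed Seed for the common-random-number simulations.
#' @param tol_pct Stop when the achieved mean is within this many percentage
#'   points of the target (also bounded by 25 bisection steps).
#' @return An `agent_params` with calibrated `p_attend`, plus attributes
#'   `achieved_mean` and `mc_se` (Monte-Carlo standard error in percent).
#' @export
calibrate <- function(target_mean_adherence,
                      params = agent_params(),
                      config = session_config(),
                      n_sims = 400,
                      seed = 1L,
                      tol_pct = 0.5) {
  if (target_mean_adherence < 0 || target_mean_adherence >= 100)
    stop("target_mean_adherence must be in [0, 100)", call. = FALSE)
  if (n_sims < 100) stop("n_sims must be >= 100", call. = FALSE)
  spec <- make_condition("control", base_config = config)

  objective <- function(p) {
    par <- params
    par$p_attend <- p
    rates <- vapply(seq_len(n_sims), function(i) {
      run_session(config, spec, par, seed = derive_seed(seed, i),
                  game = "none", keep_events = FALSE)$record$adherence_rate
    }, numeric(1))
    c(mean = mean(rates), se = stats::sd(rates) / sqrt(n_sims))
  }

  if (target_mean_adherence == 0) {
    params$p_attend <- 0
    ev <- objective(0)
  } else {
    top <- objective(1)
    if (target_mean_adherence > top["mean"] + 3 * top["se"])
      stop(sprintf(paste0("target %.1f%% unattainable: maximum achievable mean ",
                          "adherence is %.1f%% (MC SE %.2f) given the fixed ",
                          "timing/wrong-code parameters"),
                   target_mean_adherence, top["mean"], top["se"]), call. = FALSE)
    lo <- 0; hi <- 1; mid <- 0.5
    for (it in seq_len(25)) {
      mid <- (lo + hi) / 2
      ev <- objective(mid)
      if (abs(ev["mean"] - target_mean_adherence) <= tol_pct) break
      if (ev["mean"] < target_mean_adherence) lo <- mid else hi <- mid
    }
    params$p_attend <- mid
  }
  attr(params, "achieved_mean") <- unname(ev["mean"])
  attr(params, "mc_se") <- unname(ev["se"])
  params
}
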