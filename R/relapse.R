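# The relapse process in isolation: analytic distribution of the relapse
# round for a worst-case agent (cleared symptoms, never enters another
# code), and a Monte-Carlo counterpart that goes through the same
# close_dose_window() machinery the full simulator uses. The two routes
# back each other: closed form vs simulation.

#' Analytic relapse-round distribution for a never-adhering agent
#'
#' For an agent whose symptoms have cleared and who never enters a code
#' again, miss `k` carries hazard `h_k = min(1, base * mult^(k - 1))` and
#' the first relapse falls on round `k` with probability
#' `h_k * prod_{i<k} (1 - h_i)`.
#'
#' @param config A [session_config()].
#' @param n_rounds Number of remaining dose rounds (default `n_doses`).
#' @return Data frame with `round`, `p`, plus an attribute `p_none`
#'   (probability of no relapse within `n_rounds`).
#' @examples
#' relapse_round_pmf(session_config())
#' @export
relapse_round_pmf <- function(config, n_rounds = config$n_doses) {
  h <- relapse_hazard(config, seq_len(n_rounds))
  surv <- cumprod(1 - h)
  p <- h * c(1, utils::head(surv, -1))
  out <- data.frame(round = seq_len(n_rounds), p = p)
  attr(out, "p_none") <- surv[n_rounds]
  out
}

#' Monte-Carlo relapse rounds for a never-adhering agent
#'
#' Simulates `n` sessions at the dose-window level through
#' [close_dose_window()]: the state starts with symptoms cleared and every
#' window is MISSED. Returns the relapse round of each session (`NA` when
#' no relapse occurred within `n_doses` windows).
#'
#' @param n Number of sessions.
#' @param config A [session_config()].
#' @param seed Integer seed.
#' @return Integer vector of length `n`.
#' @export
simulate_relapse_rounds <- function(n, config = session_config(), seed = 1L) {
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      st <- env_state(config)
      st$symptoms_cleared <- TRUE
      st$blur <- 0
      for (k in seq_len(config$n_doses)) {
        st <- close_dose_window(st, config, k, "MISSED")
        if (st$last_relapse_triggered) return(k)
      }
      NA_integer_
    }, integer(1))
  })
}
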