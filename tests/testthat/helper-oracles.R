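# Independent oracles and small fixtures used across the suite.

# Brute-force slide-merge oracle for one row moving toward index 1,
# written recursively (merge the pair nearest the target edge, then recurse
# on the remainder so each result tile merges at most once). Deliberately a
# different construction from the engine's iterative scan.
oracle_merge_rec <- function(v) {
  if (length(v) < 2) return(list(v = v, s = 0))
  if (v[1] == v[2]) {
    rest <- oracle_merge_rec(v[-(1:2)])
    list(v = c(2 * v[1], rest$v), s = 2 * v[1] + rest$s)
  } else {
    rest <- oracle_merge_rec(v[-1])
    list(v = c(v[1], rest$v), s = rest$s)
  }
}

oracle_slide_row <- function(row) {
  r <- oracle_merge_rec(row[row != 0])
  list(row = as.integer(c(r$v, rep(0, length(row) - length(r$v)))),
       gained = r$s)
}

# Orient a grid so that sliding toward `dir` becomes row-wise slides toward
# index 1 (test-local re-derivation, kept independent of the engine's).
oracle_slide_grid <- function(grid, dir) {
  n <- nrow(grid)
  rows_of <- switch(dir,
    left  = function(g) lapply(seq_len(n), function(i) g[i, ]),
    right = function(g) lapply(seq_len(n), function(i) rev(g[i, ])),
    up    = function(g) lapply(seq_len(n), function(j) g[, j]),
    down  = function(g) lapply(seq_len(n), function(j) rev(g[, j]))
  )
  gained <- 0
  rows <- lapply(rows_of(grid), function(r) {
    s <- oracle_slide_row(r)
    gained <<- gained + s$gained
    s$row
  })
  out <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    r <- rows[[i]]
    switch(dir,
      left  = { out[i, ] <- r },
      right = { out[i, ] <- rev(r) },
      up    = { out[, i] <- r },
      down  = { out[, i] <- rev(r) }
    )
  }
  list(grid = out, gained = gained)
}

# A game_state with a chosen grid (bypasses spawning).
make_state <- function(grid, score = 0L) {
  g <- new_game(seed = 1)
  g$grid <- matrix(as.integer(grid), 4, 4)
  g$score <- as.integer(score)
  g$over <- is_over(g$grid)
  g
}

# Agent that deterministically succeeds/fails.
perfect_agent <- function(...) {
  agent_params(p_attend = 1, symptom_free_mult = 1, timing_sd_s = 0,
               p_wrong_code = 0, ...)
}
absent_agent <- function(...) agent_params(p_attend = 0, ...)

# Mean adherence of an arm simulated with per-participant substreams.
sim_arm_mean <- function(arm, params, n = 300, master = 424242,
                         config = session_config()) {
  spec <- make_condition(arm, base_config = config)
  mean(vapply(seq_len(n), function(i)
    run_session(config, spec, params, seed = derive_seed(master, i),
                game = "none", keep_events = FALSE)$record$adherence_rate,
    numeric(1)))
}
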