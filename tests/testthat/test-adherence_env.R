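# The illness overlay: dose schedule, entry classification, relapse hazard,
# blur dynamics, window closure bookkeeping, earnings.

test_that("schedule_doses returns one time per minute and respects invariants", {
  cfg <- session_config()
  expect_equal(schedule_doses(cfg), seq(60, 840, by = 60))
  expect_length(schedule_doses(cfg), 14)
  expect_lte(max(schedule_doses(cfg)), cfg$session_duration_s)
  expect_equal(schedule_doses(session_config(n_doses = 1)), 60)
  expect_error(session_config(n_doses = 15), "exceeds")
  expect_error(session_config(relapse_base_p = 1.5), "relapse_base_p")
})

test_that("classify_entry partitions correctly for any window in (0, 30)", {
  for (w in c(5, 15, 29)) {
    cfg <- session_config(on_time_window_s = w)
    sched <- 60 * 3
    expect_equal(classify_entry(cfg, 3, sched, cfg$code), "CORRECT_ON_TIME")
    expect_equal(classify_entry(cfg, 3, sched + w, cfg$code), "CORRECT_ON_TIME")
    expect_equal(classify_entry(cfg, 3, sched - w, cfg$code), "CORRECT_ON_TIME")
    expect_equal(classify_entry(cfg, 3, sched + w + 1, cfg$code), "CORRECT_OFF_TIME")
    expect_equal(classify_entry(cfg, 3, sched, "nope"), "WRONG_CODE")
    expect_equal(classify_entry(cfg, 3, NA, NA), "MISSED")
  }
  cfg <- session_config()  # window 15: +45 s is off time
  expect_equal(classify_entry(cfg, 1, 60 + 45, cfg$code), "CORRECT_OFF_TIME")
})

test_that("relapse hazard starts at 2%, doubles per miss, and caps at 1", {
  cfg <- session_config()
  expect_equal(relapse_hazard(cfg, 1), 0.02)
  expect_equal(relapse_hazard(cfg, 2:4), c(0.04, 0.08, 0.16))
  expect_equal(relapse_hazard(cfg, 7), 1)    # 0.02 * 2^6 = 1.28, capped
  expect_error(relapse_hazard(cfg, 0), "no miss")
})

test_that("probability of a relapse within 6 misses matches the product formula", {
  cfg <- session_config()
  h <- relapse_hazard(cfg, 1:6)
  p_analytic <- 1 - prod(1 - h)
  expect_equal(p_analytic, 0.822018101, tolerance = 1e-8)
  rounds <- simulate_relapse_rounds(20000, cfg, seed = 303)
  p_mc <- mean(!is.na(rounds) & rounds <= 6)
  se <- sqrt(p_analytic * (1 - p_analytic) / 20000)
  expect_lt(abs(p_mc - p_analytic), 3 * se)
})

test_that("blur clears linearly and clearance is permanent", {
  cfg <- session_config()
  st <- env_state(cfg)
  st$doses_taken <- 3L
  expect_equal(update_blur(st, cfg)$blur, 1 - 3 / 7)
  st$doses_taken <- 7L
  st <- update_blur(st, cfg)
  expect_equal(st$blur, 0)
  expect_true(st$symptoms_cleared)
  # elongated arm: 7 of 14 correct entries leaves blur at one half
  cfg2 <- session_config(clear_after_doses = 14)
  st2 <- env_state(cfg2)
  st2$doses_taken <- 7L
  st2 <- update_blur(st2, cfg2)
  expect_equal(st2$blur, 0.5)
  expect_false(st2$symptoms_cleared)
})

test_that("pre-clearance misses carry no hazard and do not move the miss counter", {
  cfg <- session_config(relapse_base_p = 1)  # any draw would certainly relapse
  st <- env_state(cfg)
  st <- close_dose_window(st, cfg, 1, "MISSED")
  expect_equal(st$consecutive_misses, 0L)
  expect_false(st$relapsed)
})

test_that("a relapse adds exactly the blur increment and records the round once", {
  cfg <- session_config(relapse_base_p = 1)
  st <- env_state(cfg)
  st$symptoms_cleared <- TRUE
  st$blur <- 0
  st <- close_dose_window(st, cfg, 4, "MISSED")
  expect_true(st$relapsed && st$last_relapse_triggered)
  expect_equal(st$blur, 0.25)
  expect_equal(st$relapse_round, 4L)
  # max_relapses = 1: a second certain-relapse miss is suppressed
  st <- close_dose_window(st, cfg, 5, "MISSED")
  expect_equal(st$relapse_round, 4L)
  expect_equal(st$blur, 0.25)
  expect_false(st$last_relapse_triggered)
})

test_that("on-time entries reset the miss counter; off-time counts the pill only", {
  cfg <- session_config()
  st <- env_state(cfg)
  st$symptoms_cleared <- TRUE
  st$blur <- 0
  set.seed(1)
  st <- close_dose_window(st, cfg, 1, "MISSED")
  st <- close_dose_window(st, cfg, 2, "MISSED")
  expect_equal(st$consecutive_misses, 2L)
  st <- close_dose_window(st, cfg, 3, "CORRECT_ON_TIME")
  expect_equal(st$consecutive_misses, 0L)
  expect_equal(st$doses_taken, 1L)
  expect_equal(st$n_on_time, 1L)
  # off-time: pill counter moves, miss counter keeps counting
  st <- close_dose_window(st, cfg, 4, "CORRECT_OFF_TIME")
  expect_equal(st$doses_taken, 2L)
  expect_equal(st$n_on_time, 1L)
  expect_equal(st$consecutive_misses, 1L)
})

test_that("window bookkeeping rejects double closes and out-of-range windows", {
  cfg <- session_config()
  st <- env_state(cfg)
  st <- close_dose_window(st, cfg, 1, "MISSED")
  expect_error(close_dose_window(st, cfg, 1, "MISSED"), "already closed")
  expect_error(close_dose_window(st, cfg, 15, "MISSED"), "capped")
  for (k in 2:14) st <- close_dose_window(st, cfg, k, "MISSED")
  expect_false(st$codes_effective)
  expect_error(close_dose_window(st, cfg, 3, "MISSED"), "already closed")
})

test_that("blur stays in [0, 1] under arbitrary outcome sequences", {
  set.seed(77)
  for (rep in 1:25) {
    cfg <- session_config(
      relapse_base_p = runif(1), relapse_multiplier = 1 + runif(1, 0, 3),
      relapse_blur_increment = runif(1), max_relapses = sample(1:5, 1),
      clear_after_doses = sample(1:14, 1))
    st <- env_state(cfg)
    for (k in 1:14) {
      st <- close_dose_window(st, cfg, k, sample(adhersim:::DOSE_OUTCOMES, 1))
      expect_gte(st$blur, 0)
      expect_lte(st$blur, 1)
    }
    expect_lte(st$relapse_count, cfg$max_relapses)
  }
})

test_that("earnings start at the show-up fee, add the incentive bonus, and cap", {
  cfg <- session_config(condition = "incentive")
  st <- env_state(cfg)
  expect_equal(st$earnings, 80)
  st$n_on_time <- 1L
  st <- apply_earnings(st, cfg)
  expect_equal(st$earnings, 85)  # 80 + one Rs 5 bonus, no game score yet
  st$cumulative_game_score <- 1e7
  st <- apply_earnings(st, cfg)
  expect_equal(st$earnings, 500)
  # control arm pays no bonus
  cfg0 <- session_config()
  st0 <- env_state(cfg0)
  st0$n_on_time <- 14L
  expect_equal(apply_earnings(st0, cfg0)$earnings, 80)
})
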