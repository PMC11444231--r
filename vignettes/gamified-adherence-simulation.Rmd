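---
title: "Gamified behavioral simulation of medication adherence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamified behavioral simulation of medication adherence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhersim)
```

## The model

adhersim simulates a laboratory analog of a short antibiotic course.
A session lasts 870 s. The participant plays 2048 ("everyday life") while a
medication code must be entered once per minute — 14 dose windows, one per
scheduled minute, modeling a 7-day twice-daily regimen. Illness is a screen
blur `b ∈ [0, 1]` that starts at 1 and impairs play; each correct code entry
(on or off time) reduces blur by `initial_blur / clear_after_doses`, and
after `clear_after_doses` correct entries the screen stays clear
(`symptoms_cleared`). Once clear, each window without an on-time correct
entry is a "miss": the m-th consecutive miss triggers a relapse with hazard

    h(m) = min(1, 0.02 · 2^(m−1)),

and a relapse adds 0.25 to blur. An on-time correct entry resets the miss
counter; sessions allow at most one relapse by default (every relapsed human
participant relapsed exactly once). Earnings are
`min(500, 80 + score · score_rupee_rate [+ 5 per on-time entry in the
incentive arm])` rupees.

Each dose window classifies its entry into exactly one of four outcomes:
`CORRECT_ON_TIME` (code matches, |entry − schedule| ≤ 15 s),
`CORRECT_OFF_TIME`, `WRONG_CODE`, `MISSED`. Adherence is
`100 · #CORRECT_ON_TIME / 14`: only on-time correct entries count, matching
the separation between "correct and on time" and "correct but at the wrong
time" in the original adherence statistic. Off-time entries still advance
the pill counter and the blur schedule (a pill was taken), but count toward
the post-clearance miss/hazard branch — arriving off schedule does not
protect against relapse.

### Arms

* **control** — as above.
* **incentive** — Rs 5 per on-time entry; illness mechanics untouched.
* **reminder** — a popup at each scheduled dose time (default 3 s visible:
  "a few seconds" is unquantified in the protocol); illness mechanics
  untouched.
* **commitment** — a signed sticker; the environment is *identical* to
  control, the effect (if any) is agent-side.
* **elongated** — `clear_after_doses` doubles to 14: symptoms take twice as
  long to disappear.

A property test asserts the "mechanics untouched" claims by running a
cue-blind agent under identical seeds in control/incentive/reminder and
diffing the event logs.

## Synthetic participants

The original experiment ran 509 humans; no behavioral equations exist for
them. The agents here are therefore deliberately minimal, built around the
qualitative drivers reported for real patients — forgetfulness, symptom-free
lapses, responsiveness to cues:

* attendance: per-dose Bernoulli with
  `p = p_attend · (symptom_free_mult if cleared else 1)`, then each active
  cue closes a fraction of the remaining gap, `p ← p + x(1 − p)` for
  reminder compliance `r`, incentive sensitivity `g`, commitment boost `k`;
* timing: Gaussian jitter (SD `timing_sd_s`), rounded to whole seconds and
  truncated to the dose's open half-interval; offsets beyond ±15 s become
  off-time entries;
* code errors: wrong code with probability `p_wrong_code`;
* play: expected `skill · (1 − blur_impairment · b)` points per second
  (stochastically rounded), or — in `game = "engine"` mode — actual play of
  the bundled 2048 engine at one move attempt per second with success
  probability `1 − blur_impairment · b`.

### Defaults, with units and rationale

| parameter | default | why |
|---|---|---|
| `p_attend` | 0.6875 | calibrated (below) so control mean adherence ≈ 44% |
| `symptom_free_mult` | 0.5 | symptom-free lapses halve attendance; a mid-range value consistent with "being symptom-free" as a leading nonadherence driver |
| `reminder_compliance` | 0.82 | calibrated so the reminder arm ≈ 67% |
| `incentive_sensitivity` | 0.25 | modest boost: the arm trended up (+8 points) without reaching significance |
| `commitment_boost` | 0 | the arm changed nothing for humans |
| `timing_sd_s` | 12.4 s | gives P(|offset| > 15 s) ≈ 0.21, echoing the 21% off-time share among entries |
| `p_wrong_code` | 0.07 | 7% of entries were wrong codes |
| `skill` | 20 pts/s | a clear-screen session yields ≈17,000 points → ≈Rs 440 before the cap |
| `blur_impairment` | 0.9 | a fully blurred screen is "very difficult", not impossible |

`timing_sd_s` and `p_wrong_code` cannot be identified individually from the
published aggregate proportions (which pool all arms and are denominated by
all windows); these defaults are approximate by construction and marked so.

### Calibration

`calibrate()` bisects on `p_attend` (everything else fixed) against the
simulated control-arm mean adherence, using common random numbers across
candidate values so the objective is monotone; it reports the achieved mean
and its Monte-Carlo standard error, and refuses targets above the ceiling
implied by the fixed timing/wrong-code parameters. The shipped default was
produced by `calibrate(44)` and then frozen; at 1,000 agents the control arm
lands at 44.3% (MC SE ≈ 0.35). Calibration is linear-identifiable in the
homogeneous setting (no jitter, no wrong codes, `symptom_free_mult = 1`),
where expected adherence is exactly `100 · p_attend` — a test exploits this
for parameter recovery.

## What a green test does and does not establish

The generator emulates: the dose schedule and window classification, blur
dynamics and clearance, the doubling relapse hazard (relapse rounds
concentrate late in the session, as in the human data, because clearance
itself tends to happen late), arm-specific cue responses, and reproducible
per-participant randomness. It does **not** emulate: within-person
heterogeneity (default agents are exchangeable, so simulated within-arm SDs
are ≈11–13 points against ≈27 for humans, and simulated F statistics are
correspondingly larger), learning or strategy ("clear the screen, then stop
entering"), post-relapse behavior change, or any between-site/individual
covariates. Green simulation tests therefore establish internal consistency
of the stated world and the *direction* of intervention effects — not that
the human effect sizes are recovered. The published arm means, the
73-relapser count, and Table-2 proportions are human data: the package
reproduces the published *statistics* exactly from the published summaries,
and reproduces the *structure* (arm sizes, window counts) of the experiment,
but makes no acceptance claim that simulation matches human arm means other
than the two calibrated targets.

## Numerical choices

* **On-time window**: ±15 s (25% of the interval). The protocol never
  defines "on time"; classification tests pass for any half-width in
  (0, 30) s, and the window is a config field.
* **ANOVA from summaries**: `SSB = Σ nᵢ(x̄ᵢ − x̄)²`, `SSW = Σ (nᵢ−1)sᵢ²` —
  an algebraic identity with the raw-data decomposition, tested to 1e-9
  relative tolerance against `stats::oneway.test`/`lm` on simulated data.
  Degenerate inputs (one group, all-zero variance) are rejected.
* **Bonferroni convention**: m = 10 (all pairs among 5 arms). Back-solving
  the four published control-vs-treatment intervals yields a common critical
  value ≈2.8194 = t(504) at two-sided 0.05/10, so that convention is adopted;
  critical values come from the t distribution at `df_within`, never the
  normal approximation. With m = 1 the interval reduces exactly to the
  unadjusted pooled-variance CI, and widths increase monotonically in m.
* **Printed-precision agreement**: recomputed CI bounds agree with the
  published ones within one printed ULP (0.01); the reminder pair gets ±0.02
  because its bounds recompute to −33.974/−11.726 from the two-decimal
  published means — the last digit depends on unrounded source data. The
  commitment upper bound (9.972 vs printed 9.98) sits on the same rounding
  boundary.
* **Seeding**: a master seed plus a counter-based splitter (`derive_seed`,
  two multiplicative-congruential rounds mod 2³¹−1, exact in doubles) gives
  every participant an isolated substream; arm sizes can change without
  reshuffling anyone else's draws, and swapping two seeds swaps the records.
* **Time model**: events are stamped in whole seconds. Blur only changes at
  window closures, so score accrual is evaluated per constant-blur segment —
  numerically identical to 1 s ticks and ~50× faster; `game = "engine"`
  keeps the true tick-by-tick path.
* **Score-to-rupees**: linear at 420 rupees per 20,000 points, capped at
  Rs 500 — invented (only "rewarded on how well they scored" is stated) and
  configurable. Cumulative session score sums across game restarts.

## Design choices where the design was open

* *Hazard bookkeeping*: "doubled each time the code was not entered" is read
  as consecutive misses with reset on an on-time entry (both cumulative
  and no-reset variants would need extra state the protocol never mentions);
  the exponent caps the hazard at 1 by the 7th consecutive miss.
* *Off-time entries and the hazard*: counted into the miss/hazard branch.
  The adherence statistic separates on-time from off-time, and a protective
  off-time entry would make the elongated arm's relapse process nearly
  vacuous.
* *Pre-clearance misses* carry no hazard and do not advance the miss
  counter — the relapse consequence is explicitly tied to the cleared
  screen.
* *Commitment* is agent-side only with default effect 0; modeling it as an
  environment change would contradict the arm's definition.
* *Entries between windows* are attributed to their window by construction
  (jitter is truncated to the window's open interval).

## Known limitations

Homogeneous default agents (variance understated; per-parameter Beta/Normal
population spreads would fix this and the machinery accepts custom
`agent_params` per run); no learning, satiation, or post-relapse adaptation;
the published 63/21/7 entry-classification percentages are internally
inconsistent with the published arm means (they imply a 91% attempt rate
versus a ≈52% pooled on-time mean) and are therefore treated as approximate
texture, not calibration targets; real-money incentives, instructional
videos, and recruitment logistics are out of scope.
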