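Package: adhersim
Title: Gamified Behavioral Simulation of Antibiotic Medication Adherence
Version: 0.1.0
Authors@R:
    person("adhersim", "developers", email = "adhersim@example.org",
           role = c("aut", "cre"))
Description: A headless, seeded re-implementation of a gamified laboratory
    analog of antibiotic adherence. Everyday life is a 2048 sliding-tile
    game, illness is a blurred screen, treatment is a per-minute code entry,
    and adherence is the fraction of the 14 scheduled entries made correctly
    and on time. The package provides the deterministic game engine, the
    illness/medication overlay (dose windows, blur dynamics, a doubling
    relapse hazard, rupee earnings), five trial arms (control, incentive,
    reminder, commitment device, elongated symptom duration), stochastic
    synthetic participants with calibration utilities, an experiment harness
    with reproducible per-participant random substreams, and the trial
    statistics: one-way ANOVA with partial eta squared and Bonferroni
    simultaneous confidence intervals, computable from raw records or from
    published group summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
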