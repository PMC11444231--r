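# The trial statistics: per-arm adherence summaries, one-way ANOVA with
# partial eta squared computed from (n, mean, SD) triplets — algebraically
# identical to the raw-data ANOVA — Bonferroni simultaneous confidence
# intervals on pairwise mean differences using the pooled within-group
# variance, and the entry-classification and relapse-round tables. A
# reproduction mode recomputes the published headline statistics from the
# published group summaries alone.

#' Adherence rate of one participant
#'
#' Adherence is the percentage of scheduled doses whose code entry was
#' correct and on time: `100 * n_correct_on_time / n_doses`. Off-time
#' correct entries count as pills taken but not as adherent doses.
#'
#' @param x Either a character vector of per-dose outcomes (see
#'   [classify_entry()]) or a participant record row with
#'   `n_correct_on_time` and `n_doses`.
#' @return Percentage in \[0, 100\].
#' @examples
#' adherence_rate(c(rep("CORRECT_ON_TIME", 7), rep("MISSED", 7)))  # 50
#' @export
adherence_rate <- function(x) {
  if (is.character(x)) {
    stopifnot(all(x %in% DOSE_OUTCOMES))
    return(100 * sum(x == "CORRECT_ON_TIME") / length(x))
  }
  stopifnot(all(c("n_correct_on_time", "n_doses") %in% names(x)))
  100 * x$n_correct_on_time / x$n_doses
}

# Round half away from zero (Table-1 style whole-percent rounding).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-arm adherence summaries
#'
#' @param records Participant records from [run_experiment()].
#' @return Data frame with one row per condition: `label`, `n`, `mean`,
#'   `sd` (sample SD, denominator n - 1), and `mean_rounded` (whole percent,
#'   half away from zero).
#' @export
summarize_groups <- function(records) {
  stopifnot(all(c("condition", "adherence_rate") %in% names(records)))
  labs <- unique(records$condition)
  out <- do.call(rbind, lapply(labs, function(g) {
    r <- records$adherence_rate[records$condition == g]
    data.frame(label = g, n = length(r), mean = mean(r),
               sd = stats::sd(r), stringsAsFactors = FALSE)
  }))
  out$mean_rounded <- round_half_away(out$mean)
  rownames(out) <- NULL
  out
}

#' Build a group-summary table by hand
#'
#' @param label,n,mean,sd Parallel vectors of group label, sample size,
#'   mean adherence (percent) and sample SD (percent).
#' @return Data frame in the layout of [summarize_groups()].
#' @export
group_summary <- function(label, n, mean, sd) {
  stopifnot(length(label) == length(n), length(n) == length(mean),
            length(mean) == length(sd))
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  data.frame(label = as.character(label), n = as.integer(n),
             mean = as.numeric(mean), sd = as.numeric(sd),
             stringsAsFactors = FALSE)
}

#' Published per-arm adherence summaries
#'
#' The five (n, mean, SD) triplets reported for the human experiment:
#' control 104 (44.16, 27.45), incentive 106 (52.02, 29.41), reminder 97
#' (67.01, 27.17), commitment 102 (45.17, 26.50), elongated 100
#' (53.57, 29.05). These are inputs for the reproduction mode, not outputs
#' of this package's simulator.
#'
#' @return Data frame usable with [anova_from_summary()].
#' @export
published_group_summaries <- function() {
  group_summary(
    label = c("control", "incentive", "reminder", "commitment", "elongated"),
    n     = c(104, 106, 97, 102, 100),
    mean  = c(44.16, 52.02, 67.01, 45.17, 53.57),
    sd    = c(27.45, 29.41, 27.17, 26.50, 29.05))
}

#' One-way ANOVA from group summaries
#'
#' Computes the between- and within-group sums of squares directly from the
#' (n, mean, SD) triplets — `SSB = sum n_i (mean_i - grand_mean)^2`,
#' `SSW = sum (n_i - 1) sd_i^2` — which is algebraically identical to the
#' raw-data one-way ANOVA. Effect size is partial eta squared
#' `SSB / (SSB + SSW)`.
#'
#' @param summaries Data frame with columns `label`, `n`, `mean`, `sd`
#'   ([summarize_groups()], [group_summary()], or
#'   [published_group_summaries()]).
#' @return An `anova_summary`: `F`, `df_between`, `df_within`, `p`, `eta2p`,
#'   `ms_within`, plus the underlying sums of squares and grand mean.
#' @examples
#' anova_from_summary(published_group_summaries())
#' @export
anova_from_summary <- function(summaries) {
  stopifnot(all(c("label", "n", "mean", "sd") %in% names(summaries)))
  k <- nrow(summaries)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(summaries$n < 2)) stop("each group needs n >= 2", call. = FALSE)
  n <- summaries$n; m <- summaries$mean; s <- summaries$sd
  N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  if (ssw == 0 && ssb == 0)
    stop("zero between- and within-group variance: F undefined", call. = FALSE)
  df_b <- k - 1L
  df_w <- as.integer(N - k)
  Fstat <- (ssb / df_b) / (ssw / df_w)
  structure(
    list(F = Fstat, df_between = df_b, df_within = df_w,
         p = stats::pf(Fstat, df_b, df_w, lower.tail = FALSE),
         eta2p = ssb / (ssb + ssw),
         ms_within = ssw / df_w,
         ssb = ssb, ssw = ssw, grand_mean = grand),
    class = "anova_summary")
}

#' @export
print.anova_summary <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.2f, p = %.3g, partial eta^2 = %.3f\n",
              x$df_between, x$df_within, x$F, x$p, x$eta2p))
  invisible(x)
}

#' Bonferroni simultaneous confidence intervals for pairwise differences
#'
#' For each requested pair (i, j) the interval is
#' `diff +/- t(df_within, 1 - alpha / (2 m)) * sqrt(ms_within (1/n_i + 1/n_j))`
#' with `diff = mean_i - mean_j` and `ms_within` the pooled within-group
#' variance from [anova_from_summary()]. The default adjusts for all
#' `choose(k, 2)` pairwise comparisons (m = 10 with five arms), the
#' convention the published intervals follow. Adjusted p-values are
#' `min(1, m * p_unadjusted)`.
#'
#' @param summaries Group-summary data frame.
#' @param pairs Two-column matrix (or list of length-2 vectors) of group
#'   labels; default every pair.
#' @param alpha Simultaneous significance level (default 0.05).
#' @param m Number of comparisons adjusted for; default `choose(k, 2)`.
#' @return Data frame with `group_i`, `group_j`, `diff`, `lo`, `hi`,
#'   `p_adj`, `m`.
#' @examples
#' bonferroni_cis(published_group_summaries(),
#'                pairs = cbind("control", c("incentive", "reminder")))
#' @export
bonferroni_cis <- function(summaries, pairs = NULL, alpha = 0.05, m = NULL) {
  an <- anova_from_summary(summaries)
  labs <- summaries$label
  if (is.null(pairs)) {
    idx <- utils::combn(seq_along(labs), 2)
    pairs <- cbind(labs[idx[1, ]], labs[idx[2, ]])
  }
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.character(pairs), ncol = 2)
  unknown <- setdiff(unique(as.vector(pairs)), labs)
  if (length(unknown) > 0)
    stop("unknown groups in pairs: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(m)) m <- choose(length(labs), 2)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  tcrit <- stats::qt(1 - alpha / (2 * m), an$df_within)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- match(pairs[r, 1], labs); j <- match(pairs[r, 2], labs)
    d <- summaries$mean[i] - summaries$mean[j]
    se <- sqrt(an$ms_within * (1 / summaries$n[i] + 1 / summaries$n[j]))
    tval <- d / se
    data.frame(group_i = labs[i], group_j = labs[j], diff = d,
               lo = d - tcrit * se, hi = d + tcrit * se,
               p_adj = min(1, m * 2 * stats::pt(-abs(tval), an$df_within)),
               m = m, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pooled entry-classification table
#'
#' Counts and percentages of the four dose outcomes pooled across all
#' records, denominated both by attempted entries (on-time + off-time +
#' wrong code) and by all scheduled windows.
#'
#' @param records Participant records.
#' @return Data frame with `outcome`, `count`, `pct_of_entries` (NA for
#'   MISSED), `pct_of_windows`.
#' @export
entry_classification_table <- function(records) {
  cols <- c(CORRECT_ON_TIME = "n_correct_on_time",
            CORRECT_OFF_TIME = "n_correct_off_time",
            WRONG_CODE = "n_wrong_code", MISSED = "n_missed")
  stopifnot(all(cols %in% names(records)), nrow(records) >= 1)
  counts <- vapply(cols, function(cl) sum(records[[cl]]), numeric(1))
  entries <- sum(counts[c("CORRECT_ON_TIME", "CORRECT_OFF_TIME", "WRONG_CODE")])
  windows <- sum(counts)
  data.frame(
    outcome = names(cols),
    count = as.integer(counts),
    pct_of_entries = ifelse(names(cols) == "MISSED", NA_real_,
                            100 * counts / entries),
    pct_of_windows = 100 * counts / windows,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Distribution of the relapse round
#'
#' Among participants who relapsed, the percentage whose (single) relapse
#' occurred at each dose round.
#'
#' @param records Participant records.
#' @return Data frame with `round`, `count`, `pct`; zero rows if nobody
#'   relapsed.
#' @export
relapse_round_table <- function(records) {
  r <- records$relapse_round[!is.na(records$relapse_round)]
  if (length(r) == 0)
    return(data.frame(round = integer(0), count = integer(0), pct = numeric(0)))
  tab <- table(r)
  data.frame(round = as.integer(names(tab)),
             count = as.integer(tab),
             pct = 100 * as.integer(tab) / length(r),
             row.names = NULL)
}

#' Reproduce the published headline statistics from published summaries
#'
#' Runs [anova_from_summary()] and [bonferroni_cis()] on the published five
#' (n, mean, SD) triplets — no simulation involved. The four
#' control-versus-treatment intervals use the all-pairs (m = 10) Bonferroni
#' adjustment.
#'
#' @return List with `summaries`, `anova`, and `cis` (control minus each
#'   treatment).
#' @examples
#' rp <- reproduce_paper()
#' rp$anova
#' @export
reproduce_paper <- function() {
  pub <- published_group_summaries()
  trt <- setdiff(pub$label, "control")
  list(summaries = pub,
       anova = anova_from_summary(pub),
       cis = bonferroni_cis(pub, pairs = cbind("control", trt)))
}
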