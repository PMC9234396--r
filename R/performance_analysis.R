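#' @title Performance scoring and pattern analyses
#' @description
#' A choice is correct when it equals the pattern's majority feedback
#' outcome, regardless of the feedback actually shown on that trial.
#' Overall accuracy is computed over the 93 scored trials per 100-trial
#' block; individual above-chance performance uses a chi-square threshold
#' on that count. Beyond global accuracy, performance is analysed per
#' pattern (normalised by presentation count) and per category of
#' patterns, because different learning strategies predict different
#' per-pattern signatures that a single overall score cannot distinguish.
#' @name performance-analysis
NULL

#' Score one participant's responses against the correct outcomes
#'
#' @param responses One participant's response rows (training phase rows
#'   are scored; test rows, if present, are ignored here).
#' @param design A `wpt_design` table.
#' @return List with `per_pattern` (data frame: pattern, n_presented,
#'   n_correct, normalized_correct; correctness `NA` for the two balanced
#'   patterns) and `total_correct` / `n_scored` over scored trials.
#' @export
score_responses <- function(responses, design = wpt_design()) {
  design <- .assert_design(design)
  train <- if (is.null(responses$phase)) responses else
    responses[responses$phase == "train", , drop = FALSE]
  .assert_pattern(train$pattern)
  co <- correct_outcome(train$pattern, design)
  correct <- train$choice == co   # NA on the balanced patterns
  pat <- factor(train$pattern, levels = .WPT_PATTERNS)
  n_presented <- as.integer(table(pat))
  n_correct <- as.integer(tapply(correct, pat,
                                 function(x) sum(x, na.rm = TRUE),
                                 default = 0L))
  per <- data.frame(
    pattern = .WPT_PATTERNS,
    n_presented = n_presented,
    n_correct = ifelse(.WPT_PATTERNS %in% .WPT_UNSCORED, NA_integer_,
                       n_correct),
    stringsAsFactors = FALSE
  )
  per$normalized_correct <- per$n_correct / per$n_presented
  list(per_pattern = per,
       total_correct = sum(correct, na.rm = TRUE),
       n_scored = sum(!is.na(correct)))
}

#' Two-cell chi-square statistic for k correct of n
#'
#' Goodness-of-fit statistic of (k, n - k) against an even split:
#' `(2k - n)^2 / n`, identical to the two-cell chi-square with expected
#' counts (n/2, n/2).
#'
#' @param k Correct choices.
#' @param n Scored trials.
#' @return The chi-square(1) statistic.
#' @export
chance_chisq_stat <- function(k, n) (2 * k - n)^2 / n

#' Individual above-chance threshold
#'
#' Smallest number of correct choices k such that the two-cell chi-square
#' statistic reaches the chi-square(1 df) critical value at `alpha`; for
#' 93 scored trials and alpha = 0.05 this is 56. An exact-binomial
#' variant (smallest k with two-tailed binomial p <= alpha) is available
#' for comparison.
#'
#' @param n_scored Number of scored trials.
#' @param alpha Significance level.
#' @param exact Logical; use the exact binomial test instead of the
#'   chi-square approximation.
#' @return Integer threshold count.
#' @export
above_chance_threshold <- function(n_scored, alpha = 0.05, exact = FALSE) {
  stopifnot(n_scored >= 1, alpha > 0, alpha < 1)
  ks <- seq.int(ceiling(n_scored / 2), n_scored)
  if (exact) {
    p <- vapply(ks, function(k)
      stats::binom.test(k, n_scored)$p.value, numeric(1L))
    return(ks[which(p <= alpha)[1L]])
  }
  crit <- stats::qchisq(1 - alpha, df = 1L)
  ks[which(chance_chisq_stat(ks, n_scored) >= crit)[1L]]
}

# per-participant totals and per-pattern normalized scores for a cohort
.cohort_scores <- function(responses, design) {
  ids <- unique(responses$participant_id)
  lapply(stats::setNames(ids, ids), function(id)
    score_responses(responses[responses$participant_id == id, , drop = FALSE],
                    design))
}

#' Global performance analysis for a cohort
#'
#' Per-participant correct counts over the scored trials, the individual
#' above-chance threshold, exclusion of below-threshold participants, and
#' the group one-sample t-test against the chance mean (half the scored
#' trials).
#'
#' @param responses Cohort response rows.
#' @param design A `wpt_design` table.
#' @param alpha Significance level for the individual threshold.
#' @return List: `per_participant` (id, total_correct, above_chance),
#'   `threshold`, `included_ids`, `group_test` (one-sample t vs n/2 over
#'   all participants).
#' @export
global_performance <- function(responses, design = wpt_design(),
                               alpha = 0.05) {
  scores <- .cohort_scores(responses, design)
  totals <- vapply(scores, `[[`, numeric(1L), "total_correct")
  n_scored <- scores[[1L]]$n_scored
  thr <- above_chance_threshold(n_scored, alpha)
  per <- data.frame(participant_id = names(totals),
                    total_correct = unname(totals),
                    above_chance = unname(totals) >= thr,
                    stringsAsFactors = FALSE)
  list(per_participant = per,
       n_scored = n_scored,
       threshold = thr,
       included_ids = per$participant_id[per$above_chance],
       group_test = one_sample_t(per$total_correct, mu = n_scored / 2,
                                 label = "total correct vs chance"))
}

#' Outcome-choice bias analysis
#'
#' Normalises each participant's raw A and B choice counts on scored
#' trials by the number of scored trials whose correct answer is A and B
#' respectively (46 and 47 per 100-trial block), and tests the two
#' normalised rates against each other with a paired t-test. A rate of
#' 1.0 on both sides means choice frequencies match the answer base
#' rates.
#'
#' @param responses Cohort response rows.
#' @param design A `wpt_design` table.
#' @return List: `per_participant` (id, normalized_A, normalized_B) and
#'   `test` (paired t, A vs B).
#' @export
bias_analysis <- function(responses, design = wpt_design()) {
  design <- .assert_design(design)
  n_A_correct <- scored_trial_count(design, "A")
  n_B_correct <- scored_trial_count(design, "B")
  train <- responses[responses$phase == "train" &
                       !responses$pattern %in% .WPT_UNSCORED, , drop = FALSE]
  ids <- unique(responses$participant_id)
  per <- do.call(rbind, lapply(ids, function(id) {
    ch <- train$choice[train$participant_id == id]
    data.frame(participant_id = id,
               normalized_A = sum(ch == "A") / n_A_correct,
               normalized_B = sum(ch == "B") / n_B_correct,
               stringsAsFactors = FALSE)
  }))
  list(per_participant = per,
       test = paired_t(per$normalized_A, per$normalized_B,
                       label = "snow vs sun choice rate"))
}

#' Per-pattern performance matrix for a cohort
#'
#' @param responses Cohort response rows.
#' @param design A `wpt_design` table.
#' @param ids Participants to include (default all).
#' @return Numeric matrix of normalised correct choices, participants
#'   (rows) by the 12 answerable patterns (columns).
#' @export
pattern_performance <- function(responses, design = wpt_design(),
                                ids = unique(responses$participant_id)) {
  scores <- .cohort_scores(
    responses[responses$participant_id %in% ids, , drop = FALSE], design)
  m <- t(vapply(scores, function(s)
    stats::setNames(s$per_pattern$normalized_correct,
                    s$per_pattern$pattern)[scored_patterns()],
    numeric(length(scored_patterns()))))
  rownames(m) <- names(scores)
  m
}

#' Per-pattern above-chance tests
#'
#' Two-tailed one-sample t-tests of each answerable pattern's normalised
#' correct-choice rate against 0.5, across participants.
#'
#' @param perf Matrix from [pattern_performance()].
#' @return Data frame, one row per pattern: mean, sd, t, df, p, dz, n.
#' @export
pattern_analysis <- function(perf) {
  rows <- lapply(colnames(perf), function(p) {
    res <- .safe_stat(one_sample_t(perf[, p], mu = 0.5, label = p),
                      "one_sample_t", p, nrow(perf))
    data.frame(pattern = p, mean = mean(perf[, p]),
               sd = stats::sd(perf[, p]), res,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-category performance matrix
#'
#' Pools each category's two patterns: correct choices over presentations
#' summed within the category, per participant.
#'
#' @param responses Cohort response rows.
#' @param design A `wpt_design` table.
#' @param ids Participants to include.
#' @return Numeric matrix, participants by the six category labels.
#' @export
category_performance <- function(responses, design = wpt_design(),
                                 ids = unique(responses$participant_id)) {
  scores <- .cohort_scores(
    responses[responses$participant_id %in% ids, , drop = FALSE], design)
  cats <- pattern_categories()
  m <- t(vapply(scores, function(s) {
    per <- s$per_pattern
    vapply(cats, function(pp) {
      i <- per$pattern %in% pp
      sum(per$n_correct[i]) / sum(per$n_presented[i])
    }, numeric(1L))
  }, numeric(length(cats))))
  rownames(m) <- names(scores)
  colnames(m) <- names(cats)
  m
}

#' Category-level analysis
#'
#' Chance tests per category, the repeated-measures omnibus across the
#' six categories, and all uncorrected pairwise post-hoc comparisons.
#'
#' @param cat_perf Matrix from [category_performance()].
#' @return List: `means` (category means and sds), `chance_tests`
#'   (one-sample t vs 0.5 per category), `omnibus` ([rm_anova()]),
#'   `posthoc` ([posthoc_pairwise()]).
#' @export
category_analysis <- function(cat_perf) {
  chance <- do.call(rbind, lapply(colnames(cat_perf), function(cc)
    cbind(data.frame(category = cc, mean = mean(cat_perf[, cc]),
                     sd = stats::sd(cat_perf[, cc]),
                     stringsAsFactors = FALSE),
          .safe_stat(one_sample_t(cat_perf[, cc], mu = 0.5, label = cc),
                     "one_sample_t", cc, nrow(cat_perf)))))
  rownames(chance) <- NULL
  list(means = chance[, c("category", "mean", "sd")],
       chance_tests = chance,
       omnibus = rm_anova(cat_perf),
       posthoc = posthoc_pairwise(cat_perf))
}

#' Test-phase (singleton probe) analysis
#'
#' Scores the four no-feedback singleton probes per participant, split
#' into the highly predictive pair \{0001, 1000\} and the less predictive
#' pair \{0010, 0100\} (each 0-2). Tests: overall total against 2 of 4,
#' each pair against 1 of 2, and strong vs weak pair (paired).
#' Participants without test rows are dropped and counted.
#'
#' @param responses Cohort response rows (phase "test" rows used).
#' @param design A `wpt_design` table.
#' @param ids Participants to include.
#' @return List: `per_participant` (id, strong, weak, total),
#'   `n_missing`, and `tests` (data frame of the four group tests).
#' @export
test_phase_analysis <- function(responses, design = wpt_design(),
                                ids = unique(responses$participant_id)) {
  test <- responses[responses$phase == "test" &
                      responses$participant_id %in% ids, , drop = FALSE]
  strong <- c("0001", "1000"); weak <- c("0010", "0100")
  have <- intersect(ids, unique(test$participant_id))
  n_missing <- length(ids) - length(have)
  if (length(have) < 2L)
    stop("need >= 2 participants with test responses", call. = FALSE)
  per <- do.call(rbind, lapply(have, function(id) {
    tr <- test[test$participant_id == id, ]
    ok <- tr$choice == correct_outcome(tr$pattern, design)
    data.frame(participant_id = id,
               strong = sum(ok[tr$pattern %in% strong]),
               weak = sum(ok[tr$pattern %in% weak]),
               stringsAsFactors = FALSE)
  }))
  per$total <- per$strong + per$weak
  n <- nrow(per)
  tests <- rbind(
    .safe_stat(one_sample_t(per$total, mu = 2,
                            label = "test total vs chance (2/4)"),
               "one_sample_t", "test total vs chance (2/4)", n),
    .safe_stat(one_sample_t(per$strong, mu = 1,
                            label = "strong pair vs chance (1/2)"),
               "one_sample_t", "strong pair vs chance (1/2)", n),
    .safe_stat(one_sample_t(per$weak, mu = 1,
                            label = "weak pair vs chance (1/2)"),
               "one_sample_t", "weak pair vs chance (1/2)", n),
    .safe_stat(paired_t(per$strong, per$weak, label = "strong vs weak pair"),
               "paired_t", "strong vs weak pair", n)
  )
  list(per_participant = per, n_missing = n_missing, tests = tests)
}
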