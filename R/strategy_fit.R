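#' @title Least-squares strategy-fit scores
#' @description
#' A participant's adherence to a strategy is measured by a normalised
#' least-squares score: over the patterns shown in an analysis window, the
#' sum of squared differences between the observed number of outcome-A
#' choices and the number expected under the strategy profile, divided by
#' the sum of squared presentation counts. Scores lie in \[0, 1\]; 0 is a
#' perfect match, and scores below 0.1 flag candidate strategies. Because
#' several idealised profiles make similar predictions over so few trials,
#' more than one strategy typically falls under the criterion — the fit of
#' different strategies cannot be compared statistically at the individual
#' level, so attribution here is descriptive, never declared significant.
#' @name strategy-fit
NULL

#' Analysis windows
#'
#' The full task plus the first and second halves (blocks of 50 trials per
#' 100-trial repeat; for the 200-trial variant the blocks are trials
#' 1-100 and 101-200).
#'
#' @param design A `wpt_design` table.
#' @return Named list of inclusive `c(first, last)` trial ranges with
#'   labels `full`, `block1`, `block2`.
#' @export
fit_windows <- function(design = wpt_design()) {
  n <- sum(.assert_design(design)$n_total)
  list(full = c(1L, n),
       block1 = c(1L, n %/% 2L),
       block2 = c(n %/% 2L + 1L, n))
}

# per-pattern presentation and A-choice counts within a trial range
.window_counts <- function(responses, window) {
  train <- if (is.null(responses$phase)) responses else
    responses[responses$phase == "train", , drop = FALSE]
  keep <- train$trial_index >= window[1] & train$trial_index <= window[2]
  train <- train[keep, , drop = FALSE]
  if (nrow(train) == 0L)
    stop("analysis window contains no trials", call. = FALSE)
  n_p <- table(factor(train$pattern, levels = .WPT_PATTERNS))
  obs_A <- table(factor(train$pattern[train$choice == "A"],
                        levels = .WPT_PATTERNS))
  list(n = as.numeric(n_p), obs_A = as.numeric(obs_A),
       pattern = .WPT_PATTERNS)
}

#' Strategy-fit score for one participant and window
#'
#' `score = sum_p (obsA_p - n_p * P_s(A|p))^2 / sum_p n_p^2`, with `n_p`
#' and `obsA_p` the presentations and A choices of pattern p inside the
#' window. Patterns not shown in the window contribute nothing. By default
#' all 14 patterns enter the sums (profiles prescribe behaviour on the two
#' balanced patterns even though accuracy is undefined there); set
#' `scored_only = TRUE` to restrict to the 12 answerable patterns.
#'
#' @param responses One participant's response rows (training phase).
#' @param profile A `strategy_profile`.
#' @param window Inclusive trial range `c(first, last)`; see
#'   [fit_windows()].
#' @param scored_only Logical; drop the two balanced patterns from both
#'   sums.
#' @return Score in \[0, 1\].
#' @export
fit_score <- function(responses, profile, window = c(1L, 100L),
                      scored_only = FALSE) {
  wc <- .window_counts(responses, window)
  keep <- if (scored_only) !wc$pattern %in% .WPT_UNSCORED else
    rep(TRUE, length(wc$pattern))
  exp_A <- wc$n * as.numeric(profile[wc$pattern])
  sum((wc$obs_A[keep] - exp_A[keep])^2) / sum(wc$n[keep]^2)
}

#' Fit every strategy in every window, for every participant
#'
#' @param responses Response rows for one or more participants
#'   (`participant_id`, `trial_index`, `pattern`, `choice`, `phase`).
#' @param design A `wpt_design` table (defines the windows).
#' @param windows Named list of trial ranges; defaults to
#'   [fit_windows()].
#' @param criterion Fit criterion; scores strictly below it flag candidate
#'   strategies.
#' @param scored_only Passed to [fit_score()].
#' @return Data frame of class `wpt_fits`: `participant_id`, `window`,
#'   `strategy`, `score`, `under_criterion`, plus `true_strategy` carried
#'   through when present.
#' @export
fit_all <- function(responses, design = wpt_design(),
                    windows = fit_windows(design), criterion = 0.1,
                    scored_only = FALSE) {
  stopifnot(all(c("participant_id", "trial_index", "pattern", "choice")
                %in% names(responses)))
  ids <- unique(responses$participant_id)
  truth <- if ("true_strategy" %in% names(responses)) {
    stats::setNames(responses$true_strategy[!duplicated(responses$participant_id)],
                    ids)
  }
  rows <- lapply(ids, function(id) {
    rr <- responses[responses$participant_id == id, , drop = FALSE]
    per_window <- lapply(names(windows), function(w) {
      sc <- vapply(.WPT_STRATEGIES, function(s) {
        fit_score(rr, strategy_profile(s, design), windows[[w]],
                  scored_only = scored_only)
      }, numeric(1L))
      data.frame(participant_id = id, window = w,
                 strategy = .WPT_STRATEGIES, score = unname(sc),
                 under_criterion = unname(sc) < criterion,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_window)
  })
  out <- do.call(rbind, rows)
  if (!is.null(truth)) out$true_strategy <- truth[out$participant_id]
  rownames(out) <- NULL
  class(out) <- c("wpt_fits", "data.frame")
  out
}

#' Count of strategies under the criterion, per participant and window
#'
#' @param fits A `wpt_fits` table from [fit_all()].
#' @return Data frame `participant_id`, `window`, `n_under_criterion`.
#' @export
under_criterion_counts <- function(fits) {
  agg <- stats::aggregate(under_criterion ~ participant_id + window,
                          data = fits, FUN = sum)
  names(agg)[3] <- "n_under_criterion"
  agg
}

#' Best-fitting strategies for one participant and window
#'
#' All strategies whose score is within `tolerance` of the minimum *and*
#' under the criterion. Ties are returned together (no forced winner);
#' the set is empty when no score beats the criterion.
#'
#' @param scores Named numeric vector of 12 scores (names = strategies).
#' @param criterion Fit criterion (default 0.1).
#' @param tolerance Tie tolerance; scores are ratios of small integers for
#'   deterministic profiles, so exact ties are meaningful.
#' @return Character vector of strategy names (possibly empty).
#' @export
best_fit <- function(scores, criterion = 0.1, tolerance = 1e-12) {
  stopifnot(length(scores) == length(.WPT_STRATEGIES),
            !is.null(names(scores)))
  hit <- scores < criterion & scores <= min(scores) + tolerance
  names(scores)[hit]
}

#' Strategy-recovery confusion matrix
#'
#' Attributes each simulated participant to the best-fitting strategy in
#' one window and cross-tabulates attribution against the generating
#' strategy. Ties are counted as "ambiguous", an empty candidate set as
#' "none". Rows sum to the number of agents per true strategy.
#'
#' @param fits A `wpt_fits` table carrying `true_strategy` (from a cohort
#'   built by [simulate_cohort()]).
#' @param window Window label, default "full".
#' @param criterion,tolerance Passed to [best_fit()].
#' @return Integer matrix, true strategies (rows) by attributed strategies
#'   plus "ambiguous" and "none" (columns).
#' @export
recovery_confusion <- function(fits, window = "full", criterion = 0.1,
                               tolerance = 1e-12) {
  stopifnot("true_strategy" %in% names(fits))
  ff <- fits[fits$window == window, , drop = FALSE]
  ids <- unique(ff$participant_id)
  attributed <- vapply(ids, function(id) {
    fi <- ff[ff$participant_id == id, ]
    hits <- best_fit(stats::setNames(fi$score, fi$strategy),
                     criterion, tolerance)
    if (length(hits) == 0L) "none"
    else if (length(hits) > 1L) "ambiguous"
    else hits
  }, character(1L))
  truth <- vapply(ids, function(id)
    ff$true_strategy[ff$participant_id == id][1L], character(1L))
  cols <- c(.WPT_STRATEGIES, "ambiguous", "none")
  tab <- table(factor(truth, levels = .WPT_STRATEGIES),
               factor(attributed, levels = cols))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(true = rownames(tab), attributed = cols))
  m[rowSums(m) > 0 | rownames(m) %in% unique(truth), , drop = FALSE]
}
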