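#' @title The modified Weather Prediction Task design
#' @description
#' The task shows 1 to 3 of 4 cues on each trial (a "pattern", coded as a
#' 4-character presence string, cue 1 to cue 4 left to right) and gives
#' probabilistic feedback: outcome A ("snow") or outcome B ("sun"). Cues 1
#' and 4 are highly predictive (0.80 marginal association with B and A,
#' respectively); cues 2 and 3 are less predictive (0.60 with B and A).
#' The marginal probabilities are realised exactly by fixed per-pattern
#' occurrence counts over a 100-trial block: 14 patterns, 50 trials ending
#' in each outcome, each cue present on 50 trials.
#'
#' Two patterns (0110 and 1001) pair cues of equal predictiveness pointing
#' to opposite outcomes; their feedback is split evenly, so they have no
#' correct answer and are excluded from accuracy scoring, leaving 93 scored
#' trials (46 with correct answer A, 47 with B) per 100-trial block.
#' @name wpt-design
NULL

# canonical per-pattern occurrence counts for one 100-trial block,
# patterns in lexicographic order, cue1..cue4 read left to right
.WPT_PATTERNS <- c("0001", "0010", "0011", "0100", "0101", "0110", "0111",
                   "1000", "1001", "1010", "1011", "1100", "1101", "1110")
.WPT_N_A <- c(8L, 4L, 12L, 1L, 5L, 1L, 9L, 1L, 2L, 1L, 2L, 1L, 2L, 1L)
.WPT_N_B <- c(1L, 1L, 1L, 3L, 1L, 2L, 1L, 8L, 2L, 6L, 1L, 12L, 3L, 8L)

# the two balanced patterns with no correct answer
.WPT_UNSCORED <- c("0110", "1001")

# marginal cue-outcome associations: index, predictiveness, outcome
.WPT_CUE_ROLES <- data.frame(
  cue            = 1:4,
  predictiveness = c("high", "low", "low", "high"),
  outcome        = c("B", "B", "A", "A"),
  probability    = c(0.80, 0.60, 0.60, 0.80),
  stringsAsFactors = FALSE
)

#' Outcome display labels
#'
#' Outcome A is displayed as "snow" and outcome B as "sun". Internal logic
#' uses the A/B enumeration; CSV files store the display strings.
#'
#' @param outcome Character vector of "A"/"B" codes or "snow"/"sun" labels.
#' @return For [outcome_display()], the display labels; for
#'   [outcome_code()], the A/B codes.
#' @examples
#' outcome_display(c("A", "B"))
#' outcome_code("snow")
#' @export
outcome_display <- function(outcome) {
  stopifnot(all(outcome %in% c("A", "B")))
  c(A = "snow", B = "sun")[outcome]
}

#' @rdname outcome_display
#' @export
outcome_code <- function(outcome) {
  stopifnot(all(outcome %in% c("snow", "sun")))
  c(snow = "A", sun = "B")[outcome]
}

#' The 14 valid cue patterns
#'
#' Valid patterns are the 4-character binary strings with 1 to 3 cues
#' present (the all-cue and no-cue displays never occur).
#'
#' @return Character vector of the 14 pattern codes, lexicographic order.
#' @export
wpt_patterns <- function() .WPT_PATTERNS

#' Build the canonical trial-count design table
#'
#' Returns the fixed pattern-by-outcome occurrence table of the modified
#' WPT. With `n_repeats = 1` this is the 100-trial design; `n_repeats = 2`
#' doubles every cell for the 200-trial variant.
#'
#' @param n_repeats Positive integer; number of 100-trial blocks.
#' @return A data frame of class `wpt_design` with columns `pattern`,
#'   `n_outcome_A`, `n_outcome_B`, `n_total` and attribute `n_repeats`.
#' @examples
#' d <- wpt_design()
#' sum(d$n_total)        # 100
#' sum(d$n_outcome_A)    # 50
#' @export
wpt_design <- function(n_repeats = 1L) {
  if (length(n_repeats) != 1L || is.na(n_repeats) || n_repeats < 1 ||
      n_repeats != as.integer(n_repeats)) {
    stop("`n_repeats` must be a single positive integer", call. = FALSE)
  }
  n_repeats <- as.integer(n_repeats)
  out <- data.frame(
    pattern     = .WPT_PATTERNS,
    n_outcome_A = .WPT_N_A * n_repeats,
    n_outcome_B = .WPT_N_B * n_repeats,
    stringsAsFactors = FALSE
  )
  out$n_total <- out$n_outcome_A + out$n_outcome_B
  attr(out, "n_repeats") <- n_repeats
  class(out) <- c("wpt_design", "data.frame")
  out
}

.assert_design <- function(design) {
  stopifnot(is.data.frame(design),
            all(c("pattern", "n_outcome_A", "n_outcome_B") %in% names(design)))
  if (is.null(design$n_total))
    design$n_total <- design$n_outcome_A + design$n_outcome_B
  design
}

.assert_pattern <- function(pattern) {
  bad <- !pattern %in% .WPT_PATTERNS
  if (any(bad)) {
    stop("invalid pattern code(s): ", paste(unique(pattern[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(pattern)
}

#' Correct outcome of a pattern
#'
#' The correct answer for a pattern is its majority feedback outcome.
#' Patterns 0110 and 1001 combine two equally predictive cues pointing to
#' opposite outcomes: they predict both outcomes equally and have no
#' correct answer (`NA`) by design, even though the small odd occurrence
#' count of 0110 cannot realise an exactly even feedback split.
#'
#' @param pattern Character vector of pattern codes.
#' @param design A `wpt_design` table.
#' @return Character vector of "A", "B" or `NA`.
#' @examples
#' correct_outcome("0001")  # "A"
#' correct_outcome("1001")  # NA
#' @export
correct_outcome <- function(pattern, design = wpt_design()) {
  design <- .assert_design(design)
  .assert_pattern(pattern)
  i <- match(pattern, design$pattern)
  ifelse(design$pattern[i] %in% .WPT_UNSCORED |
           design$n_outcome_A[i] == design$n_outcome_B[i], NA_character_,
         ifelse(design$n_outcome_A[i] > design$n_outcome_B[i], "A", "B"))
}

#' Marginal cue-outcome association probability
#'
#' Probability, over all trials containing the cue, that the feedback is
#' the cue's associated outcome (B for cues 1-2, A for cues 3-4). Invariant
#' to the number of 100-trial repeats.
#'
#' @param cue_index Integer in 1..4.
#' @param design A `wpt_design` table.
#' @param outcome Optional outcome ("A" or "B") to condition on instead of
#'   the cue's associated outcome.
#' @return A probability.
#' @examples
#' cue_outcome_probability(4)         # 0.80, association with A
#' cue_outcome_probability(1, outcome = "A")  # 0.20
#' @export
cue_outcome_probability <- function(cue_index, design = wpt_design(),
                                    outcome = NULL) {
  if (length(cue_index) != 1L || !cue_index %in% 1:4)
    stop("`cue_index` must be a single integer in 1..4", call. = FALSE)
  design <- .assert_design(design)
  if (is.null(outcome))
    outcome <- .WPT_CUE_ROLES$outcome[cue_index]
  stopifnot(outcome %in% c("A", "B"))
  has_cue <- substr(design$pattern, cue_index, cue_index) == "1"
  n_out <- if (outcome == "A") design$n_outcome_A else design$n_outcome_B
  sum(n_out[has_cue]) / sum(design$n_total[has_cue])
}

#' Cue roles
#'
#' @return Data frame with one row per cue: index, predictiveness
#'   (high/low), associated outcome, and marginal association probability.
#' @export
cue_roles <- function() .WPT_CUE_ROLES

#' Number of scored trials
#'
#' Trials of the two balanced patterns (0110, 1001) have no correct answer
#' and are excluded from accuracy scoring: 93 of each 100 trials remain.
#'
#' @param design A `wpt_design` table.
#' @param outcome Optional: count only scored trials whose correct answer
#'   is this outcome ("A" gives 46 per block, "B" 47).
#' @return Integer trial count.
#' @export
scored_trial_count <- function(design = wpt_design(), outcome = NULL) {
  design <- .assert_design(design)
  scored <- !design$pattern %in% .WPT_UNSCORED
  if (is.null(outcome)) return(sum(design$n_total[scored]))
  stopifnot(outcome %in% c("A", "B"))
  keep <- scored & correct_outcome(design$pattern, design) %in% outcome
  sum(design$n_total[keep])
}

#' Scored patterns
#'
#' @return The 12 pattern codes that have a correct answer.
#' @export
scored_patterns <- function() setdiff(.WPT_PATTERNS, .WPT_UNSCORED)

#' @rdname scored_patterns
#' @export
unscored_patterns <- function() .WPT_UNSCORED

#' Pattern categories by cue congruence and predictiveness
#'
#' The 12 answerable patterns pool into six pairs sharing cue composition:
#' each category pairs a pattern with its mirror image under swapping the
#' roles of the two outcomes. The two balanced patterns belong to no
#' category.
#'
#' @return Named list of six character vectors of length 2.
#' @examples
#' pattern_categories()[["two congruent cues"]]
#' @export
pattern_categories <- function() {
  list(
    "one highly predictive cue" = c("0001", "1000"),
    "one less predictive cue" = c("0010", "0100"),
    "two congruent cues" = c("0011", "1100"),
    "one highly predictive cue and one incongruent less predictive cue" =
      c("0101", "1010"),
    "two congruent cues and one incongruent less predictive cue" =
      c("0111", "1110"),
    "two congruent cues and one incongruent highly predictive cue" =
      c("1011", "1101")
  )
}

#' Category of a pattern
#'
#' @param pattern Character vector of pattern codes.
#' @return Category label, or `NA` for the two balanced patterns.
#' @export
pattern_category <- function(pattern) {
  .assert_pattern(pattern)
  cats <- pattern_categories()
  lookup <- stats::setNames(rep(names(cats), lengths(cats)), unlist(cats))
  unname(lookup[pattern])
}
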