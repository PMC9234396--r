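#' @title Idealised learning-strategy response profiles
#' @description
#' Each named strategy is an idealised decision rule mapping every cue
#' pattern to a probability of choosing outcome A (snow). A responder
#' adhering strictly to a strategy answers deterministically (probability 0
#' or 1) on patterns the rule decides, and at chance (0.5) on patterns it
#' leaves undetermined. Twelve strategies are modelled, from answering
#' every pattern correctly (multicue) through partial rules (hierarchical,
#' equal weight, congruent cues, two most predictive cues, the four
#' one-cue rules, singleton, singleton strong) down to fully undetermined
#' responding.
#' @name strategy-profiles
NULL

.WPT_STRATEGIES <- c("multicue", "hierarchical", "equal_weight",
                     "one_cue_1000", "two_most_predictive", "one_cue_0001",
                     "congruent_cues", "one_cue_0010", "one_cue_0100",
                     "singleton", "singleton_strong", "undetermined")

# aliases from earlier nomenclatures, accepted as synonyms
.STRATEGY_ALIASES <- c(
  perfect               = "multicue",
  all_but_two_strong    = "hierarchical",
  all_but_two_strong_cards = "hierarchical",
  two_vs_one            = "equal_weight",
  single_cue_strong_1000 = "one_cue_1000",
  single_cue_strong_0001 = "one_cue_0001",
  single_cue_weak_0010  = "one_cue_0010",
  single_cue_weak_0100  = "one_cue_0100",
  singleton_prototypes  = "congruent_cues",
  random                = "undetermined"
)

#' Strategy names
#'
#' @param aliases Logical; include accepted synonyms from earlier
#'   nomenclatures (e.g. "perfect", "random").
#' @return Character vector of the 12 canonical strategy names.
#' @export
strategy_names <- function(aliases = FALSE) {
  if (aliases) c(.WPT_STRATEGIES, names(.STRATEGY_ALIASES)) else .WPT_STRATEGIES
}

.canonical_strategy <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name %in% names(.STRATEGY_ALIASES)) name <- .STRATEGY_ALIASES[[name]]
  if (!name %in% .WPT_STRATEGIES)
    stop("unknown strategy: '", name, "'", call. = FALSE)
  name
}

# P(choose A) = 1/0 on patterns whose correct outcome the rule has learned,
# 0.5 elsewhere
.profile_learned <- function(learned, design) {
  p <- stats::setNames(rep(0.5, length(.WPT_PATTERNS)), .WPT_PATTERNS)
  co <- correct_outcome(learned, design)
  stopifnot(!anyNA(co))
  p[learned] <- ifelse(co == "A", 1, 0)
  p
}

#' Build one strategy response profile
#'
#' Returns the per-pattern probability of choosing outcome A under strict
#' adherence to the named strategy. All entries lie in \{0, 0.5, 1\};
#' profiles are defined on all 14 patterns, including the two balanced
#' patterns, so fit scores can use them.
#'
#' Rules: *multicue* answers every pattern correctly; *hierarchical*
#' answers correctly except at chance whenever both highly predictive cues
#' are present (1001, 1011, 1101) and on 0110; *equal_weight* takes an
#' unweighted cue vote (chance on ties 0101, 1010, 0110, 1001); the four
#' *one_cue* rules follow one cue's associated outcome when present and
#' choose the opposite outcome when absent; *two_most_predictive* follows
#' whichever highly predictive cue is present alone, chance otherwise;
#' *congruent_cues* learns the singletons and the two congruent two-cue
#' patterns; *singleton* the four singletons; *singleton_strong* the two
#' highly predictive singletons; *undetermined* is chance everywhere.
#'
#' @param name Strategy name (see [strategy_names()]); synonyms accepted.
#' @param design A `wpt_design` table (used for correct outcomes).
#' @return Named numeric vector over the 14 patterns, class
#'   `strategy_profile`, attribute `strategy`.
#' @examples
#' strategy_profile("hierarchical")[["1011"]]  # 0.5
#' strategy_profile("congruent_cues")[["0011"]]  # 1
#' @export
strategy_profile <- function(name, design = wpt_design()) {
  name <- .canonical_strategy(name)
  design <- .assert_design(design)
  pats <- .WPT_PATTERNS
  has <- function(cue) substr(pats, cue, cue) == "1"

  p <- switch(name,
    multicue = .profile_learned(scored_patterns(), design),
    hierarchical = {
      pr <- .profile_learned(scored_patterns(), design)
      pr[c("1011", "1101")] <- 0.5  # both strong cues present
      pr
    },
    equal_weight = {
      # unweighted vote: cues 3,4 vote A; cues 1,2 vote B; ties at chance
      votes_A <- has(3) + has(4)
      votes_B <- has(1) + has(2)
      stats::setNames(ifelse(votes_A > votes_B, 1,
                             ifelse(votes_A < votes_B, 0, 0.5)), pats)
    },
    one_cue_1000 = stats::setNames(ifelse(has(1), 0, 1), pats),
    one_cue_0001 = stats::setNames(ifelse(has(4), 1, 0), pats),
    one_cue_0010 = stats::setNames(ifelse(has(3), 1, 0), pats),
    one_cue_0100 = stats::setNames(ifelse(has(2), 0, 1), pats),
    two_most_predictive = stats::setNames(
      ifelse(has(4) & !has(1), 1, ifelse(has(1) & !has(4), 0, 0.5)), pats),
    congruent_cues = .profile_learned(
      c("0001", "0010", "0011", "0100", "1000", "1100"), design),
    singleton = .profile_learned(c("0001", "0010", "0100", "1000"), design),
    singleton_strong = .profile_learned(c("0001", "1000"), design),
    undetermined = stats::setNames(rep(0.5, length(pats)), pats)
  )
  structure(p, strategy = name, class = c("strategy_profile", "numeric"))
}

#' All twelve strategy profiles as a matrix
#'
#' @param design A `wpt_design` table.
#' @return Numeric matrix, 14 patterns (rows) by 12 strategies (columns),
#'   entries P(choose A).
#' @export
strategy_profiles <- function(design = wpt_design()) {
  m <- vapply(.WPT_STRATEGIES,
              function(s) as.numeric(strategy_profile(s, design)),
              numeric(length(.WPT_PATTERNS)))
  rownames(m) <- .WPT_PATTERNS
  m
}

#' Expected outcome-A choice counts under a profile
#'
#' For each pattern, the number of A choices expected from a strict
#' adherent given the pattern's presentation count: `n_p * P(A | p)`.
#' Non-integer on chance patterns.
#'
#' @param profile A `strategy_profile` (or named probability vector over
#'   the 14 patterns).
#' @param window_counts Named vector of presentation counts per pattern
#'   (e.g. `n_total` from a design, or observed per-block counts).
#' @return Named numeric vector of expected A counts.
#' @export
expected_A_counts <- function(profile, window_counts) {
  stopifnot(all(names(window_counts) %in% .WPT_PATTERNS),
            all(window_counts >= 0))
  miss <- setdiff(names(window_counts), names(profile))
  if (length(miss))
    stop("profile missing pattern(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  unclass(window_counts * profile[names(window_counts)])
}

#' Expected accuracy of a strategy over the scored trials
#'
#' Probability-weighted proportion of correct choices a strict adherent
#' achieves over the scored trials: deterministic entries contribute 1
#' when they match the correct outcome (0 otherwise), chance entries 0.5.
#' The two balanced patterns are excluded. Invariant to `n_repeats`.
#'
#' @param profile A `strategy_profile`.
#' @param design A `wpt_design` table.
#' @return Expected proportion correct in \[0, 1\].
#' @examples
#' expected_accuracy(strategy_profile("congruent_cues"))  # 73/93, 78.5%
#' @export
expected_accuracy <- function(profile, design = wpt_design()) {
  design <- .assert_design(design)
  sc <- design[!design$pattern %in% .WPT_UNSCORED, ]
  co <- correct_outcome(sc$pattern, design)
  pA <- as.numeric(profile[sc$pattern])
  p_correct <- ifelse(co == "A", pA, 1 - pA)
  sum(sc$n_total * p_correct) / sum(sc$n_total)
}
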