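#' @title Synthetic responder cohorts
#' @description
#' Randomised trial sequences realise the design's fixed (pattern,
#' feedback) counts exactly — feedback is a shuffle of the fixed outcome
#' multiset within each pattern, not independent Bernoulli draws — and
#' simulated agents respond to them under a named strategy with a simple
#' two-parameter noise model: an initial acquisition window of uniform
#' responding (the trials a human needs before any rule is in place)
#' followed by strategy responding with a trembling-hand lapse rate.
#' @name synthetic-cohort
NULL

.WPT_SLOTS <- c("left", "center-left", "center-right", "right")

#' Generate a randomised trial sequence
#'
#' Shuffles the design's trial multiset uniformly, so every generated
#' sequence reproduces the per-pattern feedback counts cell for cell, and
#' assigns each present cue a distinct screen slot uniformly at random.
#'
#' @param design A `wpt_design` table.
#' @param seed Integer seed; the sequence is deterministic given the seed.
#' @return Data frame with one row per trial: `trial_index`, `pattern`,
#'   `pos_cue1`..`pos_cue4` (slot name, or `""` when the cue is absent)
#'   and `feedback_outcome` ("A"/"B").
#' @export
generate_sequence <- function(design = wpt_design(), seed) {
  design <- .assert_design(design)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  withr::with_seed(as.integer(seed), {
    pattern <- rep(design$pattern, times = design$n_total)
    feedback <- unlist(Map(function(a, b) c(rep("A", a), rep("B", b)),
                           design$n_outcome_A, design$n_outcome_B),
                       use.names = FALSE)
    ord <- sample.int(length(pattern))
    pattern <- pattern[ord]
    feedback <- feedback[ord]
    pos <- t(vapply(pattern, function(p) {
      present <- substring(p, 1:4, 1:4) == "1"
      slots <- rep("", 4L)
      slots[present] <- sample(.WPT_SLOTS, sum(present))
      slots
    }, character(4L)))
  })
  out <- data.frame(
    trial_index = seq_along(pattern),
    pattern = pattern,
    pos_cue1 = pos[, 1], pos_cue2 = pos[, 2],
    pos_cue3 = pos[, 3], pos_cue4 = pos[, 4],
    feedback_outcome = feedback,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Agent configuration
#'
#' @param strategy Strategy name (see [strategy_names()]).
#' @param lapse_rate Probability in \[0, 0.5\] of inverting the strategy's
#'   choice on any post-acquisition trial (trembling hand).
#' @param acquisition_length Number of initial trials answered uniformly
#'   at random before the strategy is applied.
#' @param seed Integer seed for the agent's choices.
#' @return List of class `agent_config`.
#' @export
agent_config <- function(strategy, lapse_rate = 0.10,
                         acquisition_length = 10L, seed = 1L) {
  strategy <- .canonical_strategy(strategy)
  stopifnot(is.numeric(lapse_rate), length(lapse_rate) == 1L,
            lapse_rate >= 0, lapse_rate <= 0.5,
            is.numeric(acquisition_length), acquisition_length >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(strategy = strategy, lapse_rate = lapse_rate,
                 acquisition_length = as.integer(acquisition_length),
                 seed = as.integer(seed)),
            class = "agent_config")
}

# one choice per pattern given P(A); chance entries are genuine
# Bernoulli(0.5) draws (caller provides the RNG scope)
.draw_choices <- function(p_A, lapse) {
  base <- ifelse(stats::runif(length(p_A)) < p_A, "A", "B")
  flip <- stats::runif(length(p_A)) < lapse
  ifelse(flip, ifelse(base == "A", "B", "A"), base)
}

#' Simulate one agent's responses to a trial sequence
#'
#' For trials inside the acquisition window the choice is uniform; after
#' it, the choice is drawn from the profile's P(A | pattern) and flipped
#' with probability `lapse_rate`. The agent also answers the four
#' singleton test probes (no feedback) by the same post-acquisition rule,
#' in randomised order.
#'
#' @param sequence A trial sequence from [generate_sequence()].
#' @param agent An [agent_config()].
#' @param profile Strategy profile; defaults to the agent's strategy.
#' @param participant_id Identifier recorded on every row.
#' @return Data frame: `participant_id`, `trial_index`, `pattern`,
#'   `choice`, `phase` ("train"/"test"), `true_strategy`. Test rows are
#'   numbered beyond the last training trial.
#' @export
simulate_responses <- function(sequence, agent,
                               profile = strategy_profile(agent$strategy),
                               participant_id = "agent1") {
  stopifnot(inherits(agent, "agent_config"),
            all(c("trial_index", "pattern") %in% names(sequence)))
  miss <- setdiff(unique(sequence$pattern), names(profile))
  if (length(miss))
    stop("profile missing pattern(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(sequence)
  probes <- c("0001", "0010", "0100", "1000")
  withr::with_seed(agent$seed, {
    in_acq <- sequence$trial_index <= agent$acquisition_length
    p_A <- as.numeric(profile[sequence$pattern])
    p_A[in_acq] <- 0.5
    lapse <- ifelse(in_acq, 0, agent$lapse_rate)
    train_choice <- .draw_choices(p_A, lapse)
    probes <- sample(probes)
    test_choice <- .draw_choices(as.numeric(profile[probes]),
                                 agent$lapse_rate)
  })
  rbind(
    data.frame(participant_id = participant_id,
               trial_index = sequence$trial_index,
               pattern = sequence$pattern,
               choice = train_choice, phase = "train",
               true_strategy = agent$strategy,
               stringsAsFactors = FALSE),
    data.frame(participant_id = participant_id,
               trial_index = n + seq_along(probes),
               pattern = probes,
               choice = test_choice, phase = "test",
               true_strategy = agent$strategy,
               stringsAsFactors = FALSE)
  )
}

#' Simulate a cohort of strategy-following agents
#'
#' Each participant receives an independent randomised sequence and an
#' independent agent, with child seeds drawn reproducibly from the master
#' seed. The generating strategy is recorded on every row so recovery can
#' be scored.
#'
#' @param design A `wpt_design` table.
#' @param cohort_spec Data frame with columns `strategy`, `n` and
#'   optionally `lapse_rate`, `acquisition_length` (defaults 0.10 and 10).
#' @param master_seed Integer master seed.
#' @return List with `responses` (all participants' rows bound together)
#'   and `sequences` (named list of trial sequences per participant).
#' @examples
#' spec <- data.frame(strategy = c("hierarchical", "undetermined"), n = 2)
#' coh <- simulate_cohort(wpt_design(), spec, master_seed = 42)
#' table(coh$responses$true_strategy) / 104  # 2 agents each
#' @export
simulate_cohort <- function(design = wpt_design(), cohort_spec,
                            master_seed = 1L) {
  stopifnot(is.data.frame(cohort_spec),
            all(c("strategy", "n") %in% names(cohort_spec)),
            all(cohort_spec$n >= 1))
  if (is.null(cohort_spec$lapse_rate)) cohort_spec$lapse_rate <- 0.10
  if (is.null(cohort_spec$acquisition_length))
    cohort_spec$acquisition_length <- 10L

  per_agent <- cohort_spec[rep(seq_len(nrow(cohort_spec)), cohort_spec$n), ]
  n_agents <- nrow(per_agent)
  seeds <- withr::with_seed(as.integer(master_seed),
                            matrix(sample.int(.Machine$integer.max,
                                              2L * n_agents),
                                   ncol = 2L))
  profiles <- stats::setNames(
    lapply(unique(per_agent$strategy), strategy_profile, design = design),
    unique(per_agent$strategy))

  sequences <- vector("list", n_agents)
  responses <- vector("list", n_agents)
  ids <- sprintf("%s_%02d", per_agent$strategy,
                 stats::ave(seq_len(n_agents), per_agent$strategy,
                            FUN = seq_along))
  for (i in seq_len(n_agents)) {
    seqn <- generate_sequence(design, seed = seeds[i, 1])
    ag <- agent_config(per_agent$strategy[i],
                       lapse_rate = per_agent$lapse_rate[i],
                       acquisition_length = per_agent$acquisition_length[i],
                       seed = seeds[i, 2])
    sequences[[i]] <- seqn
    responses[[i]] <- simulate_responses(seqn, ag,
                                         profile = profiles[[ag$strategy]],
                                         participant_id = ids[i])
  }
  names(sequences) <- ids
  list(responses = do.call(rbind, responses), sequences = sequences)
}
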