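# shared fixtures and independent oracles, built in code at test time

DESIGN <- wpt_design()

# the canonical occurrence counts, restated independently of the package
# constants so design assertions do not test the code against itself
CANONICAL_COUNTS <- data.frame(
  pattern = c("0001", "0010", "0011", "0100", "0101", "0110", "0111",
              "1000", "1001", "1010", "1011", "1100", "1101", "1110"),
  n_A = c(8, 4, 12, 1, 5, 1, 9, 1, 2, 1, 2, 1, 2, 1),
  n_B = c(1, 1, 1, 3, 1, 2, 1, 8, 2, 6, 1, 12, 3, 8),
  stringsAsFactors = FALSE
)

# a noise-free agent of the given strategy responding to a fresh sequence
noise_free_agent <- function(strategy, seed, design = DESIGN,
                             id = strategy) {
  s <- generate_sequence(design, seed = seed)
  simulate_responses(s, agent_config(strategy, lapse_rate = 0,
                                     acquisition_length = 0, seed = seed + 1L),
                     participant_id = id)
}

# independent fit-score oracle: walks the window trial by trial, tallies
# observed A choices and presentations per pattern, then applies the
# normalised squared-difference formula from the tallies
fit_score_oracle <- function(responses, profile, window,
                             scored_only = FALSE) {
  tr <- responses[responses$phase == "train", ]
  obs_A <- numeric(0); n_p <- numeric(0)
  for (i in seq_len(nrow(tr))) {
    t_i <- tr$trial_index[i]
    if (t_i < window[1] || t_i > window[2]) next
    p <- tr$pattern[i]
    if (scored_only && p %in% unscored_patterns()) next
    if (is.na(n_p[p])) { n_p[p] <- 0; obs_A[p] <- 0 }
    n_p[p] <- n_p[p] + 1
    if (tr$choice[i] == "A") obs_A[p] <- obs_A[p] + 1
  }
  exp_A <- n_p * as.numeric(profile[names(n_p)])
  sum((obs_A - exp_A)^2) / sum(n_p^2)
}

# independent within-subject sums-of-squares decomposition
rm_anova_oracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  list(F = f, df1 = df1, df2 = df2,
       eta_p2 = ss_cond / (ss_cond + ss_err))
}

# random response set over a given sequence (choices carry no structure)
random_responses <- function(sequence, seed, id = "rand") {
  withr::with_seed(seed, {
    ch <- sample(c("A", "B"), nrow(sequence), replace = TRUE)
  })
  data.frame(participant_id = id, trial_index = sequence$trial_index,
             pattern = sequence$pattern, choice = ch, phase = "train",
             stringsAsFactors = FALSE)
}
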