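test_that("fit score matches hand-derived values for strict adherents", {
  r <- noise_free_agent("one_cue_0001", seed = 17)
  # the profile is deterministic on every pattern, so the self-score is 0
  expect_identical(fit_score(r, strategy_profile("one_cue_0001"), c(1, 100)), 0)
  # against multicue, the disagreements are enumerable from the design:
  # 0010 (0 vs 5), 0110 (0 vs 1.5), 1001 (4 vs 2), 1101 (5 vs 0);
  # denominator = sum of squared presentation counts = 866
  expect_equal(fit_score(r, strategy_profile("multicue"), c(1, 100)),
               (25 + 2.25 + 4 + 25) / 866)
})

test_that("an exact half-split response set scores 0 against the chance profile", {
  d2 <- wpt_design(2)  # every presentation count is even
  s <- generate_sequence(d2, seed = 8)
  ch <- character(nrow(s))
  for (p in unique(s$pattern)) {
    i <- which(s$pattern == p)
    ch[i] <- rep(c("A", "B"), each = length(i) / 2)
  }
  r <- data.frame(participant_id = "half", trial_index = s$trial_index,
                  pattern = s$pattern, choice = ch, phase = "train",
                  stringsAsFactors = FALSE)
  expect_identical(fit_score(r, strategy_profile("undetermined"), c(1, 200)), 0)
})

test_that("fit score is bounded in [0,1] and equals the trial-tally oracle", {
  s <- generate_sequence(DESIGN, seed = 5)
  profs <- lapply(setNames(nm = strategy_names()), strategy_profile)
  windows <- list(c(1L, 100L), c(1L, 50L), c(51L, 100L))
  for (i in 1:1000) {
    r <- random_responses(s, seed = i)
    prof <- profs[[(i %% 12) + 1L]]
    w <- windows[[(i %% 3) + 1L]]
    sc <- fit_score(r, prof, w)
    expect_gte(sc, 0)
    expect_lte(sc, 1)
    expect_equal(sc, fit_score_oracle(r, prof, w))
  }
  # restricted 12-pattern variant agrees with its oracle too
  r <- random_responses(s, seed = 2001)
  expect_equal(fit_score(r, profs$multicue, c(1, 100), scored_only = TRUE),
               fit_score_oracle(r, profs$multicue, c(1, 100),
                                scored_only = TRUE))
  expect_error(fit_score(r, profs$multicue, c(101, 200)), "no trials")
})

test_that("block windows condition on observed per-block presentation counts", {
  s <- generate_sequence(DESIGN, seed = 23)
  r <- random_responses(s, seed = 23)
  b1 <- fit_score(r, strategy_profile("hierarchical"), c(1, 50))
  b2 <- fit_score(r, strategy_profile("hierarchical"), c(51, 100))
  expect_equal(b1, fit_score_oracle(r, strategy_profile("hierarchical"),
                                    c(1, 50)))
  # the two blocks generally see different pattern mixes
  n1 <- table(s$pattern[1:50]); n2 <- table(s$pattern[51:100])
  expect_false(identical(n1, n2))
  expect_false(isTRUE(all.equal(b1, b2)))
})

test_that("fit_all produces 12 bounded scores per participant and window", {
  spec <- data.frame(strategy = c("hierarchical", "undetermined"), n = 2)
  coh <- simulate_cohort(DESIGN, spec, master_seed = 77)
  fits <- fit_all(coh$responses, DESIGN)
  expect_equal(nrow(fits), 4L * 3L * 12L)
  expect_true(all(fits$score >= 0 & fits$score <= 1))
  expect_equal(fits$under_criterion, fits$score < 0.1)
  cnt <- under_criterion_counts(fits)
  expect_equal(nrow(cnt), 12L)
  expect_true(all(cnt$n_under_criterion >= 0 & cnt$n_under_criterion <= 12))
})

test_that("best_fit honours criterion, minimum and ties", {
  sc <- setNames(seq(0.03, 0.25, length.out = 12), strategy_names())
  expect_equal(best_fit(sc), "multicue")
  sc2 <- sc; sc2[["hierarchical"]] <- sc2[["multicue"]]
  expect_setequal(best_fit(sc2), c("multicue", "hierarchical"))
  expect_equal(best_fit(sc + 0.10), character(0))
})

test_that("expected fit score against the true strategy is lowest, and rises with lapse", {
  # averaged over 200 seeds under the cohort's default noise conditions
  profs <- lapply(setNames(nm = strategy_names()), strategy_profile)
  n_seeds <- 200L
  mean_scores <- matrix(0, nrow = 12, ncol = 12,
                        dimnames = list(true = strategy_names(),
                                        scored = strategy_names()))
  for (seed in seq_len(n_seeds)) {
    s <- generate_sequence(DESIGN, seed = 5000 + seed)
    for (true_s in strategy_names()) {
      r <- simulate_responses(s, agent_config(true_s, lapse_rate = 0.1,
                                              acquisition_length = 10,
                                              seed = 9000 + seed),
                              profile = profs[[true_s]])
      for (m in strategy_names())
        mean_scores[true_s, m] <- mean_scores[true_s, m] +
          fit_score(r, profs[[m]], c(1, 100)) / n_seeds
    }
  }
  for (true_s in strategy_names())
    expect_equal(names(which.min(mean_scores[true_s, ])), true_s)

  # monotonicity: the self-score is non-decreasing in the lapse rate
  for (true_s in c("multicue", "congruent_cues", "one_cue_0010")) {
    self_by_lapse <- vapply(c(0, 0.1, 0.2, 0.3), function(lp) {
      mean(vapply(1:80, function(seed) {
        s <- generate_sequence(DESIGN, seed = 300 + seed)
        r <- simulate_responses(s, agent_config(true_s, lapse_rate = lp,
                                                acquisition_length = 0,
                                                seed = 600 + seed),
                                profile = profs[[true_s]])
        fit_score(r, profs[[true_s]], c(1, 100))
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(self_by_lapse) >= 0))
  }
})

test_that("noise-free recovery is diagonal for the deterministic-profile strategies", {
  one_cue <- c("one_cue_1000", "one_cue_0001", "one_cue_0010", "one_cue_0100")
  spec <- data.frame(strategy = one_cue, n = 3, lapse_rate = 0,
                     acquisition_length = 0)
  coh <- simulate_cohort(DESIGN, spec, master_seed = 13)
  fits <- fit_all(coh$responses, DESIGN)
  conf <- recovery_confusion(fits, window = "full")
  expect_equal(unname(rowSums(conf)), rep(3L, 4L))
  for (s in one_cue) expect_equal(conf[s, s], 3L)
})

test_that("undetermined-true agents are not confidently attributed elsewhere", {
  spec <- data.frame(strategy = "undetermined", n = 8)
  coh <- simulate_cohort(DESIGN, spec, master_seed = 29)
  fits <- fit_all(coh$responses, DESIGN)
  conf <- recovery_confusion(fits, window = "full")
  soft <- conf["undetermined", c("undetermined", "ambiguous", "none")]
  expect_gte(sum(soft), 5L)
})
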