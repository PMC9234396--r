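test_that("scoring judges choices against the majority outcome, not feedback", {
  s <- generate_sequence(DESIGN, seed = 2)
  # an agent that always answers A gets exactly the 46 A-correct trials
  r <- data.frame(participant_id = "allA", trial_index = s$trial_index,
                  pattern = s$pattern, choice = "A", phase = "train",
                  stringsAsFactors = FALSE)
  sc <- score_responses(r, DESIGN)
  expect_equal(sc$total_correct, 46L)
  expect_equal(sc$n_scored, 93L)
  # per-pattern fields: no correctness on the balanced patterns
  per <- sc$per_pattern
  expect_true(all(is.na(per$n_correct[per$pattern %in% unscored_patterns()])))
  expect_true(all(per$normalized_correct >= 0 & per$normalized_correct <= 1,
                  na.rm = TRUE))
  expect_equal(per$n_presented, DESIGN$n_total)
  # noise-free congruent-cues agents average 73/93 over seeds
  tot <- vapply(1:100, function(seed) {
    score_responses(noise_free_agent("congruent_cues", seed), DESIGN)$total_correct
  }, numeric(1))
  expect_equal(mean(tot), 73, tolerance = 0.02)
})

test_that("above-chance threshold reproduces the chi-square cutoffs", {
  expect_equal(above_chance_threshold(93, 0.05), 56L)
  expect_equal(round(chance_chisq_stat(56, 93), 3), 3.882)
  expect_lt(chance_chisq_stat(55, 93), qchisq(0.95, 1))
  expect_equal(above_chance_threshold(100, 0.05), 60L)
  expect_equal(above_chance_threshold(186, 0.05), 107L)
  # exact-binomial variant is at least as conservative here
  expect_gte(above_chance_threshold(93, 0.05, exact = TRUE), 56L)
  # the closed form equals the two-cell chi-square for arbitrary k
  for (k in c(47, 50, 56, 70, 93)) {
    obs <- c(k, 93 - k); expe <- c(46.5, 46.5)
    expect_equal(chance_chisq_stat(k, 93), sum((obs - expe)^2 / expe))
  }
  # k(n)/n approaches one half as n grows
  ns <- c(10, 50, 100, 200, 500)
  ratio <- vapply(ns, function(n) above_chance_threshold(n) / n, numeric(1))
  expect_true(all(diff(ratio) < 0))
})

test_that("global performance excludes below-threshold participants", {
  spec <- data.frame(strategy = c("hierarchical", "undetermined"),
                     n = c(6, 3))
  coh <- simulate_cohort(DESIGN, spec, master_seed = 201)
  gp <- global_performance(coh$responses, DESIGN)
  expect_equal(gp$threshold, 56L)
  expect_equal(nrow(gp$per_participant), 9L)
  expect_setequal(gp$included_ids,
                  gp$per_participant$participant_id[
                    gp$per_participant$total_correct >= 56])
  # hierarchical agents with modest noise pass; group test is vs 46.5
  hier <- grepl("hierarchical", gp$per_participant$participant_id)
  expect_true(all(gp$per_participant$above_chance[hier]))
  expect_equal(gp$group_test$test, "one_sample_t")
})

test_that("bias normalisation divides by the 46/47 correct-answer base rates", {
  s <- generate_sequence(DESIGN, seed = 6)
  co <- correct_outcome(s$pattern)
  # perfectly calibrated: A on the 46 A-correct, B on the 47 others
  calib <- data.frame(participant_id = "calib", trial_index = s$trial_index,
                      pattern = s$pattern,
                      choice = ifelse(is.na(co), "A", co), phase = "train",
                      stringsAsFactors = FALSE)
  allA <- calib; allA$choice <- "A"; allA$participant_id <- "allA"
  ba <- bias_analysis(rbind(calib, allA), DESIGN)
  pp <- ba$per_participant
  expect_equal(pp$normalized_A[pp$participant_id == "calib"], 1.0)
  expect_equal(pp$normalized_B[pp$participant_id == "calib"], 1.0)
  expect_equal(pp$normalized_A[pp$participant_id == "allA"], 93 / 46)
  expect_equal(pp$normalized_B[pp$participant_id == "allA"], 0)
  # raw A + raw B counts add to the scored trial count by construction
  expect_equal(pp$normalized_A * 46 + pp$normalized_B * 47, c(93, 93))
})

test_that("unbiased cohorts rarely show a significant outcome bias", {
  hits <- vapply(1:20, function(i) {
    spec <- data.frame(strategy = "undetermined", n = 12)
    coh <- simulate_cohort(DESIGN, spec, master_seed = 400 + i)
    bias_analysis(coh$responses, DESIGN)$test$p < 0.05
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("pattern and category analyses carry the strategy signatures", {
  spec <- data.frame(strategy = "hierarchical", n = 30, lapse_rate = 0,
                     acquisition_length = 0)
  coh <- simulate_cohort(DESIGN, spec, master_seed = 55)
  perf <- pattern_performance(coh$responses, DESIGN)
  expect_equal(dim(perf), c(30L, 12L))
  expect_true(all(perf >= 0 & perf <= 1))
  # noise-free hierarchical: perfect on every decided pattern
  decided <- setdiff(scored_patterns(), c("1011", "1101"))
  expect_true(all(perf[, decided] == 1))
  cp <- category_performance(coh$responses, DESIGN)
  expect_equal(colnames(cp), names(pattern_categories()))
  expect_true(all(cp[, 1:5] == 1))
  # the undecided category hovers at chance in expectation
  # (240 Bernoulli(0.5) draws: the cohort mean sits within ~4 MC sd)
  expect_lt(abs(mean(cp[, 6]) - 0.5), 0.13)
  ca <- category_analysis(cp)
  expect_equal(nrow(ca$posthoc), 15L)
  expect_equal(ca$omnibus$test, "rm_anova")
  pa <- pattern_analysis(perf[, c("1011", "1101")])
  expect_true(all(pa$p > 0.05))

  # a multicue cohort (mild noise) is above chance in all six categories
  coh2 <- simulate_cohort(DESIGN,
                          data.frame(strategy = "multicue", n = 12,
                                     lapse_rate = 0.05,
                                     acquisition_length = 0),
                          master_seed = 56)
  ca2 <- category_analysis(category_performance(coh2$responses, DESIGN))
  expect_true(all(ca2$chance_tests$p < 0.05))
  expect_true(all(ca2$chance_tests$mean > 0.5))
})

test_that("test-phase analysis splits the probes into strong and weak pairs", {
  spec <- data.frame(strategy = "singleton_strong", n = 30, lapse_rate = 0,
                     acquisition_length = 0)
  coh <- simulate_cohort(DESIGN, spec, master_seed = 91)
  tp <- test_phase_analysis(coh$responses, DESIGN)
  per <- tp$per_participant
  expect_equal(per$total, per$strong + per$weak)
  # strong singletons learned exactly; weak pair at chance in expectation
  expect_true(all(per$strong == 2L))
  expect_equal(mean(per$weak), 1, tolerance = 0.35)
  expect_equal(tp$n_missing, 0L)
  expect_equal(nrow(tp$tests), 4L)
  # participants without a test phase are dropped and counted
  drop_id <- per$participant_id[1]
  resp <- coh$responses
  resp <- resp[!(resp$participant_id == drop_id & resp$phase == "test"), ]
  tp2 <- test_phase_analysis(resp, DESIGN)
  expect_equal(tp2$n_missing, 1L)
  expect_equal(nrow(tp2$per_participant), 29L)
})
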