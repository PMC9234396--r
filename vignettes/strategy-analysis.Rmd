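---
title: "Learning-strategy analysis in the modified Weather Prediction Task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning-strategy analysis in the modified Weather Prediction Task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wptstrategy)
```

## The task and its design

The Weather Prediction Task (WPT) is a probabilistic classification task:
on each trial 1 to 3 of 4 cues appear, the respondent predicts one of two
outcomes (A, "snow", or B, "sun"), and feedback follows with fixed
per-cue probabilities. The modified design implemented here uses marginal
cue–outcome associations of 0.80 (cues 1 and 4, "highly predictive") and
0.60 (cues 2 and 3, "less predictive"), with cues 1–2 associated with B
and cues 3–4 with A.

Rather than drawing feedback independently per trial, the design fixes
the number of times each of the 14 cue patterns occurs with each
feedback outcome over a 100-trial block, so the marginal probabilities
are realised *exactly*:

```{r}
wpt_design()
```

Two consequences matter everywhere downstream:

* Patterns 0110 and 1001 pair two equally predictive cues pointing to
  opposite outcomes. They predict both outcomes equally and have no
  correct answer — note that 0110's odd occurrence count (n = 3) cannot
  realise an exactly even feedback split, so the answerless status is a
  design property, not a property of the realised counts. Accuracy is
  therefore computed over the remaining **93 scored trials** (46 with
  correct answer A, 47 with B).
* A choice is scored correct when it matches the pattern's *majority*
  outcome, never the feedback actually shown: a correct prediction can
  receive incongruent feedback, and that is the point of the task.

The 200-trial variant doubles every cell (`wpt_design(n_repeats = 2)`);
all derived probabilities are invariant to the repeat factor.

## The twelve strategy profiles

Each candidate learning strategy is idealised as a response profile:
the probability of choosing A for every pattern, always one of 0
(choose B), 1 (choose A) or 0.5 (the rule does not decide the pattern).
The profiles are constructed from the decision rules, not stored:

```{r}
strategy_profiles()[, c("multicue", "hierarchical", "congruent_cues",
                        "undetermined")]
```

Two constructions deserve comment because they are the ones a reader
might implement differently:

* The four **one-cue** rules respond with the cue's associated outcome
  when the cue is present and with the *opposite* outcome when it is
  absent — not at chance. This makes them the only fully deterministic
  profiles, which matters for exact self-fit (see below).
* The **hierarchical** rule answers every pattern correctly except when
  both highly predictive cues are present simultaneously (1001, 1011,
  1101), where the conflicting strong cues leave the choice at chance.
  It differs from **equal_weight** (an unweighted cue vote, at chance on
  the tied votes 0101/1010/0110/1001) precisely on the patterns where
  cue weighting matters.

A strict adherent's expected accuracy over the scored trials follows in
closed form; for the congruent-cues rule it is 73/93 = 78.5%. A test
cross-checks each closed form against seed-averaged noise-free
simulation.

## The fit score

Adherence of a response set to a profile is the normalised least-squares
score

$$
S = \frac{\sum_p \left(\mathrm{obsA}_p - n_p\,P(A\mid p)\right)^2}
         {\sum_p n_p^2},
$$

with $n_p$ the presentations and $\mathrm{obsA}_p$ the observed A
choices of pattern $p$ inside the analysis window (the full task or
either 50-trial block). $S \in [0,1]$; scores below the conventional
criterion 0.1 flag candidate strategies.

Numerical and design choices:

* **All 14 patterns enter both sums by default.** The profiles prescribe
  behaviour on the two answerless patterns even though accuracy is
  undefined there, and the score formula sums over "each pattern"
  without exclusion. Whether the original analyses used 14 or 12
  patterns is not determinable, so the 12-pattern variant is exposed as
  `scored_only = TRUE`; on this design the two variants differ by at
  most 25/866 in the numerator contribution.
* **Block windows condition on the observed per-block presentation
  counts**, which vary with the randomisation, not on half the design
  counts: expected counts must condition on what was actually shown.
* **Ties are resolved at tolerance 1e-12.** For deterministic profiles
  the scores are exact ratios of small integers, so exact ties are
  meaningful and are reported as such ("ambiguous"), never broken
  arbitrarily.
* **Individual-level fits are never declared significant.** The score
  is a descriptive distance; with ≤ 100 trials several profiles are
  statistically indistinguishable per participant. Inference happens
  only at the group level (repeated-measures ANOVA over the 12 per-
  participant scores, then uncorrected post-hoc paired t-tests).

## The synthetic cohort and what it does (not) emulate

Cohorts of simulated responders stand in for human participants. The
generator makes three deliberate simplifications:

* **Exact feedback counts.** Sequences shuffle the design's fixed
  (pattern, feedback) multiset, so every 100-trial sequence reproduces
  the design table cell for cell — matching how the task fixes
  presentation counts, and removing feedback-sampling noise from every
  downstream expectation.
* **Two-parameter noise.** An agent responds uniformly for an initial
  acquisition window (default 10 trials), then follows its profile with
  a trembling-hand lapse (default rate 0.10, capped at 0.5 beyond which
  the agent would systematically invert). These defaults are the
  package's study conditions: a lapse of 0.10 puts a strict adherent of
  a deterministic rule at ~90% of its ideal accuracy, about where
  successful human groups sit, and ten uniform trials is a minimal
  acquisition phase for a rule this size. Chance entries are genuine
  seeded Bernoulli(0.5) draws, not alternation.
* **No learning dynamics.** There is no trial-by-trial update rule, no
  strategy switching, and no reaction-time model. Consequently the
  cohort does *not* reproduce every qualitative feature of human data:
  for example, simulated hierarchical agents know both cue pairs
  equally well, so the test-phase advantage of highly over less
  predictive cues seen in people has no analogue here — passing tests
  on synthetic cohorts validates the analysis pipeline, not any claim
  about human learning.

Reproducibility: every random step runs under an explicit seed; cohorts
derive per-agent child seeds from one master seed, and identical master
seeds yield byte-identical output CSVs. The test-probe order is
randomised per agent (the order cannot affect any analysis).

## Statistical layer

* One-sample and paired t-tests are two-tailed and report Cohen's
  $d_z$ = (mean − μ)/sd, with the identity $|t|/\sqrt{n} = |d_z|$ used
  as a cross-check. Zero-variance input raises an error in direct calls;
  inside batch analyses (per-pattern, per-category, test phase,
  post-hoc) a degenerate comparison — typically a noise-free ceiling —
  is reported as a row of NA statistics rather than aborting the batch.
* The repeated-measures ANOVA is the univariate within-subject
  decomposition with uncorrected degrees of freedom
  (df = (c−1), (c−1)(n−1)), reporting partial
  $\eta_p^2 = SS_{cond}/(SS_{cond}+SS_{err})$. No sphericity correction
  is applied by default, matching the convention of reporting
  uncorrected df; a Greenhouse–Geisser option exists (`gg = TRUE`).
  When the condition sum of squares is numerically zero, F is reported
  as 0 rather than 0/0.
* Post-hoc comparisons are all pairwise paired t-tests, uncorrected by
  design, flagged at two-tailed p < 0.05 and p < 0.10.
* The individual above-chance threshold uses the two-cell chi-square
  statistic $(2k-n)^2/n$ against the χ²(1) critical value — 56 of 93
  at α = 0.05 — as is conventional for this task; an exact-binomial
  variant is available behind `exact = TRUE` for comparison (it is one
  count more conservative at n = 93).

## Problem sizes used in the checks

The package's own verification uses: 1,000 random response sets against
a trial-tally oracle for the fit score; 200 seeds per strategy for the
expected-self-score ordering under the default noise conditions; 80
seeds per lapse level for the noise-monotonicity property; 10,000
simulated null cohorts of n = 20 for the type-I calibration of the
one-sample t; and cohorts of 20–30 agents for the qualitative
category signatures. These sizes keep Monte-Carlo error comfortably
below the margins being asserted.

## Known limitations

* Profiles are reconstructed from the strategies' verbal decision
  rules; no external profile table exists to diff against.
* No mixture-of-strategies or change-point modelling: an agent (and an
  analysed participant) is treated as stationary within a window. The
  block windows are the only concession to strategy change.
* The recovery experiment quantifies confusability of idealised
  profiles under the package's own noise model; real participants'
  deviations from any profile are richer than lapse + acquisition.
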