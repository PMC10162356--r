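---
title: "Chunked execution of trial sequences: model, simulator, and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chunked execution of trial sequences: model, simulator, and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(chunksim)
```

## The model

When people execute a long sequence of standalone, demanding trials, the
sequence is not necessarily controlled as one unit. The account implemented
here holds that a higher-level control structure — a *program* — is
assembled before a task unit begins, and that resource limits cap the span a
single program can cover. A long sequence is therefore *chunked*: executed
as a series of smaller units, each opened by a fresh program instantiation.
Two behavioral signatures follow:

* The first trial of every chunk carries the program-assembly cost, so its
  RT is drawn from an elevated *instantiation* distribution rather than the
  *baseline* distribution.
* Dismantling the old program also dismantles the rule set nested under it,
  so the rule-switch cost is suppressed on chunk-start trials — whereas the
  Stroop congruency cost, which arises within the current trial, is not.

Formally, a sequence of `n` trials is partitioned by drawing chunk sizes
i.i.d. from a chunk-size distribution until the sequence is filled; a draw
overshooting the remaining trials is truncated to the remainder
(`sample_partition()`). Because truncation can only shorten the *final*
chunk, chunk-start positions form a renewal process, and the probability
that trial `t` begins a chunk obeys the exact recursion

```
p[1] = 1;    p[t] = sum over sizes s with t - s >= 1 of  P(s) * p[t - s]
```

implemented in `start_probabilities()` and verified, term by term, against
exhaustive enumeration of all partitions (`enumerate_partitions()`). With
small, variable chunk sizes `p[t]` rises with ordinal position — later
trials can be reached by more chunk arrangements — which is what turns
discrete RT peaks into a smooth position-wise RT ramp after averaging:

```{r}
p <- start_probabilities(10, chunk_dist_uniform(2, 9))
round(p$p, 3)
round(expected_position_rt(p), 1)
```

The expected mean RT at a position is the two-point mixture
`p[t] * mu_inst + (1 - p[t]) * mu_base` (`expected_position_rt()`); the
Monte-Carlo simulator converges to it, and the test suite holds the two
routes against each other.

## Generative parameters

Defaults of `rt_model_params()` and what pins them down:

| parameter | default | unit | rationale |
|---|---|---|---|
| `mu_inst`, `sd_inst` | 1030, 46 | ms | instantiation (chunk-start) RT distribution of the calibration data the simulation is built on |
| `mu_base`, `sd_base` | 850, 27 | ms | baseline (within-program) RT distribution |
| `switch_cost` | 75 | ms | midpoint of the reported 50–100 ms switch-cost range; suppressed at chunk starts |
| `stroop_cost` | 150 | ms | centre of the reported trial-1 congruency-cost CI [85, 210]; never suppressed |
| `err_base`, `err_switch_increment` | 0.05, 0.05 | prob. | plausible error rates; errors are independent of chunk-start status by construction |
| `rt_floor` | 150 | ms | motor floor; Normal draws are clipped (not resampled), > 15 SDs from the default means so moments are effectively untouched |
| `span_cost_per_trial` (kappa) | 25 | ms/trial | free parameter (see easy/difficult sequences below) |
| `load_cost_per_remaining_trial` (lambda) | 8 | ms/trial | free parameter |
| `sd_participant` | 0 | ms | hierarchical mode, off by default |

kappa and lambda are this package's own free parameters: only the orderings
they induce (easy trial-1 elevation, decreasing easy profile) are
empirically constrained, and the tests assert exactly those orderings, not
the magnitudes.

## What the synthetic experiments emulate

`simulate_experiment()` builds four study structures with their
study-condition defaults:

* **Probabilistic rule switching** (`exp1_switch`): 16 participants,
  250 ten-trial sequences, every transition (sequence boundary included) a
  switch with probability 0.5. Latent chunking defaults to uniform(2, 9) —
  the widest of the variable-chunking regimes, the one producing a smooth
  RT ramp rather than localized peaks.
* **Stroop** (`exp1_stroop`): the same geometry with exactly 7 congruent
  trials per 10-trial sequence (stratified, positions randomized); on
  incongruent trials the incorrect response option always repeats the
  stimulus word.
* **Strict alternation** (`exp2`): 7 participants, 300 fifteen-trial
  sequences; rules alternate every trial and the trial-1 rule alternates
  across sequences so both rules occur equally often at every position. An
  optional `participant_dists` argument gives each participant their own
  chunk-size distribution (per-participant RT-pattern heterogeneity);
  by default all share one.
* **Instructed counting** (`exp3`): 31 participants, 80 sequences of
  unpredictable length (uniform on 10..20 trials), counting covertly in 3s
  or 5s; the instruction is modelled as `fixed(count_base)` chunking, and
  `probe_answer()` gives the correct end-of-sequence probe response.
* **Easy vs difficult 8-trial sequences** (`exp4`, via `simulate_exp4()`):
  23 participants, 250 randomly interleaved sequences. Difficult sequences
  are all-switch and chunked from uniform(2, 6); easy sequences are
  all-repeat and run under a *single* program spanning all 8 trials, with
  trial-1 mean `mu_base + kappa * 8` and trial-`t` mean
  `mu_base + lambda * (8 - t)`. The program for the whole easy sequence is
  larger than the chunk-sized program that opens a difficult sequence, so
  easy trial-1 RT is *higher* (1050 vs 1030 ms expected under defaults),
  while easy RTs then *decrease* as program load decays and difficult RTs
  *increase* with the rising chunk-start probability.

Design choices worth stating. "400 iterations across 16 hypothetical
participants" is read as 400 sequences per participant for each of 16
participants; both are plain arguments. The instantiation/baseline SDs are
treated as single-level trial SDs (one Normal per trial); a hierarchical
mode (`sd_participant > 0`) adds participant-level mean offsets but is off
by default, since the calibration values describe a single distribution.
Difficult `exp4` sequences use strict alternation throughout (the original
design mixed alternation and probabilistic switching across participants;
one regime keeps the generator simple and only sharpens the qualitative
contrasts). Trial-1 switch status is defined against the final trial of the
preceding sequence; the session's very first trial has `NA` switch status
and drops out of switch-cost aggregation. Stimulus-level details (countdown
digit, font sizes, colors) are metadata only and never touch the RT model.
A chunk size of 1 is admissible only through truncation, not in the support
by default.

One run-level seed expands into per-participant substreams
(`(seed + 1000003 * i) mod 2147483647`), so identical seeds reproduce trial
tables byte-for-byte and adding participants never reshuffles earlier ones.

Named scenario presets for the cost-free illustration run
(`simulate_figure2()`) include both the body-text variable ranges
(`u2_6`, `u2_9`) and the narrower `u3_5`, `u3_6`, `u3_9` variants, plus
`fixed3`/`fixed5` and `single_program`.

```{r}
prof <- simulate_figure2("fixed3", n_participants = 8, n_sequences = 100,
                         seed = 2)
round(prof$mean_rt, 0) # peaks at positions 1, 4, 7, 10
```

## Preprocessing

`apply_exclusions()` implements the standard chain: the first 5 sequences
of each participant-session are warmup and leave all analyses (5
*sequences*, not 50 trials, so the rule transfers to 15- and variable-length
sequences); post-warmup error trials are excluded from RT but retained for
error rates; and remaining RTs outside the participant's mean ± 5 SD are
flagged in a single, non-iterative pass. The trimming statistics pool each
participant's post-warmup correct trials (a switch lets error trials enter
them). Flags are recomputed from scratch on every call, so the operation is
idempotent; zero-spread participants get no outlier flags.

One statistical caveat the tests respect: the largest standardized
deviation a sample of size `n` can contain is `(n - 1) / sqrt(n)`, so a
planted 5-SD outlier is only detectable once a participant retains roughly
30+ trials; fixtures that exercise the trimming rule therefore use longer
sequences.

## Statistics

* `position_profile()` aggregates participant-level means first, then takes
  the unweighted across-participant mean with a t-based 95% CI half-width
  (`qt(.975, n - 1) * sd / sqrt(n)`); error rates come from non-warmup
  trials so excluded errors still count against accuracy.
* `linear_contrast()` computes each participant's least-squares slope over
  centred, equally spaced position codes and t-tests the slopes against
  zero — equivalent to the classical polynomial linear contrast under
  complete balanced data. The exact contrast scaling of point-and-click
  ANOVA packages is tool-internal, so only the sign and significance of
  trend statistics are treated as reproducible quantities.
* `rm_anova_oneway()` is the classical one-way within-subject ANOVA
  (participant as block) via `stats::aov`, uncorrected degrees of freedom by
  default (`gg_correct = TRUE` applies Greenhouse–Geisser), with partial
  eta squared `SS_effect / (SS_effect + SS_error)`.
* `cost_profile()` builds switch − repeat (or incongruent − congruent)
  per-participant, per-position mean differences and runs the contrast on
  the complete cost matrix; positions missing a level for some participant
  are dropped with a warning.
* `paired_comparison()` wraps the paired t test and applies Holm's
  step-down over a supplied p-value family. Degenerate inputs are handled
  explicitly: identical vectors give `t = 0` with a zero-width CI, while
  constant non-zero differences raise a degenerate-result error instead of
  an infinite t (the same convention as a zero-variance slope set in
  `linear_contrast()`).
* `chunk_position_comparison()` pairs each participant's mean RT at the
  instructed chunk positions (4, 7, 10, 13 for 3-counting; 6, 11 for
  5-counting within the 2..15 window) against all other window positions.

Analysis windows follow the study conventions — positions 2–10, 2–15 or
2–8 depending on sequence length — with trial 1 always analysed separately.

## Numerical and testing choices

The renewal recursion is checked against enumeration marginals at 1e-12
for a battery of distributions up to `n = 12` (the enumerator refuses
`n > 15` by default; partition counts grow combinatorially and the oracle
is only needed at small `n`). Sampler frequencies are compared to exact
partition probabilities at 10,000 draws within 3 binomial SEs. Monte-Carlo
position means are compared to the analytic expectation within 3 SEs of the
appropriate two-point-mixture variance. The single-program regime's linear
contrast is run over 200 replicate simulations to confirm a false-positive
rate at the nominal 5% level (bounded at 7%). The illustration and recovery
runs use the study-condition sizes throughout (16 × 400 scenario runs,
16 × 250 and 23 × 250 experiment runs); they complete in seconds.

## What passing tests do and do not show

The generator draws trial RTs from clean Normal mixtures with homogeneous
parameters, fixed costs, and stationary chunking. Real RT data are
right-skewed, participants differ in baseline speed and cost magnitude,
costs interact with time-on-task, and spontaneous chunking need not be
stationary or i.i.d. Passing the suite therefore shows that the *pipeline*
recovers the signatures the generative account plants — rising position
profiles, declining switch costs with flat Stroop costs and error rates,
peaks at instructed chunk positions, the easy/difficult trial-1 reversal —
at the study's sample sizes; it does not by itself validate the account on
real data. The forward model is also exactly that: inferring chunk-size
distributions from data is out of scope.
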