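# Synthetic experiment generators and the trial-level RT model.

test_that("exp2 rules alternate every trial and across sequence starts", {
  set.seed(5)
  r <- generate_rule_sequence(experiment_design("exp2", n_sequences = 2))
  s1 <- r$rule[r$sequence_index == 1]
  s2 <- r$rule[r$sequence_index == 2]
  expect_equal(length(s1), 15L)
  # strict alternation within each sequence
  expect_true(all(s1[-1] != s1[-15]))
  expect_true(all(s2[-1] != s2[-15]))
  # trial-1 rule alternates across sequences: V F V F ... then F V F V ...
  expect_true(s1[1] != s2[1])
  expect_equal(s2, ifelse(s1 == "value", "font", "value"))
  # every transition, boundary included, is a switch
  expect_true(all(r$is_switch[-1]))
})

test_that("exp1 switch fraction is 0.5 within 3 binomial SEs", {
  set.seed(9)
  r <- generate_rule_sequence(experiment_design("exp1_switch",
                                                n_sequences = 250))
  within <- r$is_switch[r$position >= 2]
  n <- length(within)
  expect_equal(n, 250 * 9)
  expect_lt(abs(mean(within) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("exp3 sequence lengths are unpredictable on 10..20", {
  set.seed(2)
  r <- generate_rule_sequence(experiment_design("exp3", n_sequences = 200))
  lens <- tapply(r$position, r$sequence_index, max)
  expect_true(all(lens >= 10 & lens <= 20))
  expect_gt(length(unique(lens)), 5)
})

test_that("exp4 easy sequences contain no within-sequence switches", {
  set.seed(3)
  d <- experiment_design("exp4", n_sequences = 5)
  r <- generate_rule_sequence(d, difficulty = "easy")
  within <- r$is_switch[r$position >= 2]
  expect_false(any(within))
  rd <- generate_rule_sequence(d, difficulty = "difficult")
  expect_true(all(rd$is_switch[rd$position >= 2]))
})

test_that("unknown variants and wrong-session generators error", {
  expect_error(experiment_design("exp9"), "arg")
  expect_error(
    generate_rule_sequence(experiment_design("exp1_stroop")),
    "generate_stroop_trials"
  )
  expect_error(
    generate_stroop_trials(experiment_design("exp1_switch")),
    "exp1_stroop"
  )
})

test_that("stroop congruency is stratified exactly 7 of 10 per sequence", {
  set.seed(4)
  st <- generate_stroop_trials(experiment_design("exp1_stroop",
                                                 n_sequences = 40))
  per_seq <- tapply(st$is_congruent, st$sequence_index, sum)
  expect_true(all(per_seq == 7L))
  expect_equal(mean(st$is_congruent), 0.7)
})

test_that("stroop response options follow the congruency rules", {
  set.seed(4)
  st <- generate_stroop_trials(experiment_design("exp1_stroop",
                                                 n_sequences = 40))
  inc <- !st$is_congruent
  # incongruent: font differs from word, distractor repeats the word
  expect_true(all(st$font_color[inc] != st$word[inc]))
  expect_true(all(st$distractor[inc] == st$word[inc]))
  # congruent: font matches word, distractor is some other color
  expect_true(all(st$font_color[!inc] == st$word[!inc]))
  expect_true(all(st$distractor[!inc] != st$word[!inc]))
})

test_that("simulate_rts applies the generative means and suppressions", {
  # near-degenerate SDs expose the deterministic structure of the model
  params <- rt_model_params(sd_base = 1e-9, sd_inst = 1e-9)
  trials <- tibble::tibble(
    is_chunk_start = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    is_switch = c(FALSE, FALSE, TRUE, TRUE, NA),
    is_congruent = c(NA, NA, NA, NA, FALSE)
  )
  set.seed(1)
  out <- simulate_rts(trials, params)
  expect_equal(out$rt_ms,
               c(1030, # chunk-start repeat
                 850, # non-start repeat
                 925, # non-start switch: 850 + 75
                 1030, # chunk-start switch: cost suppressed
                 1000), # NA switch status treated as repeat; + stroop 150
               tolerance = 1e-6)
})

test_that("simulate_rts demands chunk-start flags and clips at the floor", {
  expect_error(simulate_rts(tibble::tibble(is_switch = TRUE)),
               "is_chunk_start")
  expect_error(
    simulate_rts(tibble::tibble(is_chunk_start = c(TRUE, NA))),
    "is_chunk_start"
  )
  params <- rt_model_params(mu_base = 160, sd_base = 100, mu_inst = 170,
                            sd_inst = 100, rt_floor = 150)
  set.seed(8)
  out <- simulate_rts(tibble::tibble(is_chunk_start = rep(FALSE, 2000)),
                      params)
  expect_true(all(out$rt_ms >= 150))
  expect_true(any(out$rt_ms == 150)) # clipped, not resampled
})

test_that("error rates follow err_base plus the switch increment", {
  params <- rt_model_params(err_base = 0.1, err_switch_increment = 0.15)
  n <- 40000
  set.seed(6)
  trials <- tibble::tibble(is_chunk_start = rep(c(TRUE, FALSE), n / 2),
                           is_switch = rep(c(FALSE, TRUE), each = n / 2))
  out <- simulate_rts(trials, params)
  err_rep <- mean(!out$correct[!out$is_switch])
  err_sw <- mean(!out$correct[out$is_switch])
  expect_lt(abs(err_rep - 0.10), 3 * sqrt(0.1 * 0.9 / (n / 2)))
  expect_lt(abs(err_sw - 0.25), 3 * sqrt(0.25 * 0.75 / (n / 2)))
  # chunk-start status leaves accuracy untouched
  err_start <- mean(!out$correct[out$is_chunk_start & !out$is_switch])
  err_non <- mean(!out$correct[!out$is_chunk_start & !out$is_switch])
  expect_lt(abs(err_start - err_non), 4 * sqrt(2 * 0.1 * 0.9 / (n / 4)))
})

test_that("identical seeds reproduce identical trial tables", {
  a <- simulate_experiment("exp1_switch", n_participants = 3,
                           n_sequences = 8, seed = 123)
  b <- simulate_experiment("exp1_switch", n_participants = 3,
                           n_sequences = 8, seed = 123)
  expect_identical(a, b)
  c2 <- simulate_experiment("exp1_switch", n_participants = 3,
                            n_sequences = 8, seed = 124)
  expect_false(identical(a$rt_ms, c2$rt_ms))
})

test_that("adding participants never reshuffles earlier ones", {
  small <- simulate_experiment("exp2", n_participants = 2, n_sequences = 6,
                               seed = 7)
  big <- simulate_experiment("exp2", n_participants = 4, n_sequences = 6,
                             seed = 7)
  expect_identical(small, big[big$participant %in% c("P01", "P02"), ])
})

test_that("model-true switch cost is zero at chunk starts, full elsewhere", {
  trials <- simulate_experiment("exp1_switch", n_participants = 16,
                                n_sequences = 120, seed = 31)
  inner <- trials[trials$position >= 2, ]
  cost_at <- function(rows) {
    mean(rows$rt_ms[rows$is_switch]) - mean(rows$rt_ms[!rows$is_switch])
  }
  cost_start <- cost_at(inner[inner$is_chunk_start, ])
  cost_non <- cost_at(inner[!inner$is_chunk_start, ])
  expect_lt(abs(cost_start), 5) # suppressed
  expect_lt(abs(cost_non - 75), 5) # params$switch_cost by construction
})

test_that("probe_answer counts modulo the instructed base", {
  expect_identical(probe_answer(5, 18), 3L) # 12345 12345 12345 123
  expect_identical(probe_answer(3, 10), 1L) # 123 123 123 1
  expect_identical(probe_answer(3, 1), 1L)
  expect_identical(probe_answer(5, 1), 1L)
  expect_identical(probe_answer(5, 5), 5L)
  expect_error(probe_answer(4, 10), "3 or 5")
  expect_error(probe_answer(3, 0), "positive integer")
})

test_that("hierarchical mode spreads participant means, default does not", {
  base <- simulate_figure2("single_program", n_participants = 12,
                           n_sequences = 200, seed = 15,
                           return = "participant_means")
  hier <- simulate_figure2("single_program", n_participants = 12,
                           n_sequences = 200, seed = 15,
                           params = rt_model_params(sd_participant = 60),
                           return = "participant_means")
  expect_gt(stats::sd(rowMeans(hier)), 3 * stats::sd(rowMeans(base)))
})

test_that("exp3 simulation carries its counting base and fixed chunking", {
  trials <- simulate_experiment("exp3", n_participants = 2,
                                n_sequences = 12, seed = 2, count_base = 5)
  expect_true(all(trials$count_base == 5L))
  # instructed counting is modelled as fixed(count_base) chunking
  expect_true(all(trials$position[trials$is_chunk_start] %% 5 == 1))
})
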