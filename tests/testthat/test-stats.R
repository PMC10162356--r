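# Position profiles, contrasts, RM-ANOVA, costs, paired comparisons.

test_that("position_profile matches the closed-form two-participant case", {
  trials <- constant_trials(participants = c("P01", "P02"), n_seq = 2,
                            len = 5)
  trials$rt_ms <- ifelse(trials$participant == "P01", 800, 900)
  prof <- position_profile(trials)
  expect_equal(prof$mean_rt, rep(850, 5))
  # t-based CI on the two participant means: qt(.975, 1) * sd / sqrt(2)
  expect_equal(prof$ci_rt,
               rep(stats::qt(0.975, 1) * stats::sd(c(800, 900)) / sqrt(2),
                   5))
  expect_equal(prof$mean_error, rep(0, 5))
  expect_equal(prof$n_participants, rep(2L, 5))
})

test_that("position_profile equals the hand two-stage aggregation", {
  trials <- simulate_figure2("fixed3", n_participants = 16,
                             n_sequences = 400, seed = 61,
                             return = "trials")
  trials$correct[c(10, 500, 1234)] <- FALSE # a few excluded-from-RT trials
  prof <- position_profile(trials)
  # oracle: participant-level means first, then unweighted mean across
  keep <- trials$correct
  hand <- tapply(trials$rt_ms[keep],
                 list(trials$participant[keep], trials$position[keep]),
                 mean)
  expect_equal(prof$mean_rt, unname(colMeans(hand)))
  expect_equal(prof$ci_rt,
               unname(apply(hand, 2, function(x) {
                 stats::qt(0.975, 15) * stats::sd(x) / 4
               })))
})

test_that("linear_contrast reproduces hand-computed cases", {
  # two participants with slopes 2 and 4 ms/position
  m <- rbind(2 * (1:5), 4 * (1:5))
  colnames(m) <- 1:5
  ct <- linear_contrast(m)
  expect_equal(ct$participant_slopes, c(2, 4))
  expect_equal(ct$slope_per_position, 3)
  expect_equal(ct$t, 3) # mean 3, SE = sd/sqrt(2) = 1
  expect_equal(ct$df, 1L)

  flat <- matrix(850, 4, 5, dimnames = list(NULL, 1:5))
  ct0 <- linear_contrast(flat)
  expect_equal(ct0$slope_per_position, 0)
  expect_equal(ct0$t, 0)
  expect_equal(ct0$p, 1)

  same <- rbind(2 * (1:5), 2 * (1:5))
  colnames(same) <- 1:5
  expect_error(linear_contrast(same), "degenerate")
  expect_error(linear_contrast(m[1, , drop = FALSE]), ">= 2 participants")
  expect_error(linear_contrast(m[, 1:2]), ">= 3 positions")
})

test_that("rm_anova_oneway matches a hand-computed SS decomposition", {
  # 3 participants x 3 positions; SS computed by hand from the within-
  # subject decomposition: SS_pos = n*sum((colmean-grand)^2),
  # SS_err = sum((y - rowmean - colmean + grand)^2)
  m <- rbind(c(10, 12, 17),
             c(8, 13, 15),
             c(12, 16, 19))
  n <- 3; k <- 3
  grand <- mean(m)
  ss_pos <- n * sum((colMeans(m) - grand)^2)
  resid <- sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + grand
  ss_err <- sum(resid^2)
  f_hand <- (ss_pos / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))

  res <- rm_anova_oneway(m)
  expect_equal(res$F, f_hand, tolerance = 1e-10)
  expect_equal(res$ss_effect, ss_pos, tolerance = 1e-10)
  expect_equal(res$ss_error, ss_err, tolerance = 1e-10)
  expect_equal(res$partial_eta_sq, ss_pos / (ss_pos + ss_err),
               tolerance = 1e-10)
  expect_equal(res$df_num, 2L)
  expect_equal(res$df_den, 4L)
})

test_that("rm_anova df follow (k-1, (k-1)(n-1)) and edge cases resolve", {
  set.seed(3)
  m <- matrix(rnorm(16 * 9, 850, 30), 16, 9)
  res <- rm_anova_oneway(m)
  expect_equal(res$df_num, 8L)
  expect_equal(res$df_den, 120L)

  flat <- matrix(850, 4, 5)
  res0 <- rm_anova_oneway(flat)
  expect_equal(res0$F, 0)
  expect_equal(res0$partial_eta_sq, 0)
  expect_error(rm_anova_oneway(m[, 1, drop = FALSE]), ">= 2 positions")

  gg <- rm_anova_oneway(m, gg_correct = TRUE)
  expect_equal(gg$F, res$F)
  expect_gt(gg$gg_epsilon, 1 / (ncol(m) - 1))
  expect_lte(gg$gg_epsilon, 1)
  expect_equal(gg$p, stats::pf(gg$F, gg$gg_epsilon * 8, gg$gg_epsilon * 120,
                               lower.tail = FALSE))
})

test_that("paired_comparison reproduces hand-computed values and Holm", {
  res <- paired_comparison(c(10, 20, 30), c(0, 0, 0))
  expect_equal(res$mean_diff, 20)
  expect_equal(res$t, 20 / (10 / sqrt(3)))
  expect_equal(res$df, 2)

  same <- paired_comparison(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$conf_low, 0)
  expect_equal(same$conf_high, 0)

  expect_error(paired_comparison(c(5, 6, 7), c(4, 5, 6)), "degenerate")
  expect_error(paired_comparison(1:3, 1:4), "equal length")

  # Holm step-down over the family {.01, .02, .04} -> {.03, .04, .04}
  set.seed(2)
  a <- rnorm(10, 1)
  res <- paired_comparison(a, rep(0, 10), family = c(0.02, 0.04))
  manual <- stats::p.adjust(c(res$p, 0.02, 0.04), method = "holm")[1]
  expect_equal(res$p_holm, manual)
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), method = "holm"),
               c(0.03, 0.04, 0.04))
})

test_that("cost_profile recovers the constructed switch-cost trajectory", {
  trials <- simulate_experiment("exp1_switch", n_participants = 16,
                                n_sequences = 250, seed = 71)
  trials <- apply_exclusions(trials)$trials
  cp <- cost_profile(trials, "switch", positions = 2:10)
  # model-true cost at position t is (1 - p[t]) * 75
  p <- start_probabilities(10, chunk_dist_uniform(2, 9))$p
  expected <- (1 - p[2:10]) * 75
  expect_true(all(abs(cp$profile$mean_cost - expected) < 12))
  expect_lt(cp$contrast$slope_per_position, 0)
})

test_that("stroop costs are flat because congruency ignores chunking", {
  trials <- simulate_experiment("exp1_stroop", n_participants = 16,
                                n_sequences = 250, seed = 72)
  trials <- apply_exclusions(trials)$trials
  cp <- cost_profile(trials, "stroop", positions = 2:10)
  expect_true(all(abs(cp$profile$mean_cost - 150) < 15))
  expect_gt(cp$contrast$p, 0.05)
  # the Stroop session has no rule switches, so no switch cost is defined
  expect_error(cost_profile(trials, "switch"), "condition labels")
})

test_that("chunk_position_comparison picks the instructed positions", {
  trials <- simulate_experiment("exp3", n_participants = 8,
                                n_sequences = 40, seed = 12, count_base = 3)
  res <- chunk_position_comparison(trials, 3)
  expect_equal(res$chunk_positions, c(4L, 7L, 10L, 13L))
  expect_equal(res$other_positions,
               setdiff(2:15, c(4, 7, 10, 13)))
  res5 <- chunk_position_comparison(trials, 5)
  expect_equal(res5$chunk_positions, c(6L, 11L))
  expect_error(chunk_position_comparison(trials, 4), "3 or 5")
  expect_error(chunk_position_comparison(trials, 3, position_window = 2:3),
               "empty")
})

test_that("instructed 3-counting elevates chunk positions significantly", {
  trials <- simulate_experiment("exp3", n_participants = 31,
                                n_sequences = 80, seed = 13, count_base = 3)
  trials <- apply_exclusions(trials)$trials
  res <- chunk_position_comparison(trials, 3)
  expect_gt(res$comparison$mean_diff, 0)
  expect_lt(res$comparison$p, 0.05)
  # removing the chunk positions abolishes the position effect
  keep <- setdiff(2:15, res$chunk_positions)
  m <- position_means_matrix(trials, positions = keep)
  ct <- linear_contrast(m)
  expect_gt(ct$p, 0.05)
})

test_that("statistics are invariant to row order of the trial table", {
  trials <- simulate_experiment("exp1_switch", n_participants = 4,
                                n_sequences = 30, seed = 91)
  trials <- apply_exclusions(trials)$trials
  set.seed(1)
  shuffled <- trials[sample.int(nrow(trials)), ]
  expect_equal(position_profile(trials), position_profile(shuffled))
  m1 <- position_means_matrix(trials, positions = 2:10)
  m2 <- position_means_matrix(shuffled, positions = 2:10)
  expect_equal(m1, m2)
  expect_equal(unclass(cost_profile(trials, "switch", 2:10)$contrast),
               unclass(cost_profile(shuffled, "switch", 2:10)$contrast))
})

test_that("profiles warn when a participant loses all trials in a cell", {
  trials <- constant_trials(participants = c("P01", "P02"), n_seq = 2,
                            len = 4)
  trials$correct[trials$participant == "P02" & trials$position == 3] <- FALSE
  expect_warning(prof <- position_profile(trials), "fewer participants")
  expect_equal(prof$n_participants[prof$position == 3], 1L)
})
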