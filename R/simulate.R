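#' Simulate reaction times and accuracy for a trial table
#'
#' Fills `rt_ms` and `correct` under the generative model (see
#' [rt_model_params()]): chunk-start trials draw from the instantiation
#' distribution, others from baseline; `switch_cost` is added on switch
#' trials that do not begin a chunk; `stroop_cost` is added on every
#' incongruent trial; RTs are clipped at `rt_floor`. Errors are Bernoulli
#' with probability `err_base` plus `err_switch_increment` on switch trials,
#' independent of chunk-start status.
#'
#' @param trials Trial table with logical `is_chunk_start` (no `NA`s) and,
#'   optionally, `is_switch` and `is_congruent` columns.
#' @param params An [rt_model_params()].
#' @param mu_shift Scalar added to both RT means (participant-level offset in
#'   hierarchical mode).
#' @return `trials` with `rt_ms` and `correct` filled.
#' @export
simulate_rts <- function(trials, params = rt_model_params(), mu_shift = 0) {
  stopifnot(inherits(params, "rt_model_params"))
  if (!"is_chunk_start" %in% names(trials) ||
      anyNA(trials[["is_chunk_start"]])) {
    stop("`trials` must carry complete `is_chunk_start` flags; ",
         "assign them first (see assign_chunk_starts())", call. = FALSE)
  }
  n <- nrow(trials)
  start <- trials[["is_chunk_start"]]
  sw <- if (!"is_switch" %in% names(trials)) logical(n) else
    !is.na(trials[["is_switch"]]) & trials[["is_switch"]]
  incong <- if (!"is_congruent" %in% names(trials)) logical(n) else
    !is.na(trials[["is_congruent"]]) & !trials[["is_congruent"]]

  mu <- ifelse(start, params$mu_inst, params$mu_base) + mu_shift
  sd <- ifelse(start, params$sd_inst, params$sd_base)
  rt <- stats::rnorm(n, mu, sd)
  rt <- rt + params$switch_cost * (sw & !start)
  rt <- rt + params$stroop_cost * incong
  trials$rt_ms <- pmax(rt, params$rt_floor)

  p_err <- params$err_base + params$err_switch_increment * sw
  trials$correct <- stats::runif(n) >= p_err
  trials
}

#' Simulate a full synthetic experiment
#'
#' Drives the generators end to end for one experiment variant: builds each
#' participant's rule (or Stroop) trials, samples latent chunk boundaries
#' from the design's chunk-size distribution, and simulates RTs and
#' accuracy. Each participant uses a deterministic RNG substream derived
#' from `seed`, so results are reproducible and adding participants does not
#' reshuffle earlier ones. `exp4` delegates to [simulate_exp4()].
#'
#' @param variant Experiment variant, see [experiment_design()].
#' @param n_participants,n_sequences Optional overrides of the design
#'   defaults.
#' @param params An [rt_model_params()].
#' @param dist Optional chunk-size distribution override (a [chunk_dist()]
#'   or serializable list).
#' @param participant_dists Optional list mapping participant index to a
#'   [chunk_dist()], for per-participant chunking heterogeneity
#'   (Exp-2-style); defaults to the shared design distribution.
#' @param seed Integer seed for the run.
#' @param count_base Counting base for `exp3` (3 or 5).
#' @return A trial-record [tibble::tibble()] with columns `participant`,
#'   `session`, `sequence_index`, `position`, `rule`, `is_switch`,
#'   `is_congruent`, `is_chunk_start`, `rt_ms`, `correct`, `excluded`,
#'   `exclusion_reason` (plus variant-specific metadata columns).
#' @examples
#' trials <- simulate_experiment("exp1_switch", n_participants = 2,
#'                               n_sequences = 10, seed = 1)
#' head(trials)
#' @export
simulate_experiment <- function(variant = c("exp1_switch", "exp1_stroop",
                                            "exp2", "exp3", "exp4"),
                                n_participants = NULL, n_sequences = NULL,
                                params = rt_model_params(), dist = NULL,
                                participant_dists = NULL, seed = 1,
                                count_base = 3) {
  variant <- match.arg(variant)
  design <- experiment_design(variant, n_participants = n_participants,
                              n_sequences = n_sequences,
                              count_base = count_base, dist = dist)
  if (variant == "exp4") {
    return(simulate_exp4(params = params, dist = design$dist,
                         n_participants = design$n_participants,
                         n_sequences = design$n_sequences, seed = seed))
  }
  one_participant <- function(i) {
    set.seed(participant_seed(seed, i))
    tr <- if (variant == "exp1_stroop") generate_stroop_trials(design) else
      generate_rule_sequence(design)
    d_i <- if (!is.null(participant_dists)) participant_dists[[i]] else
      design$dist
    tr <- assign_chunk_starts(tr, d_i)
    shift <- if (params$sd_participant > 0)
      stats::rnorm(1, 0, params$sd_participant) else 0
    tr <- simulate_rts(tr, params, mu_shift = shift)
    tr$participant <- sprintf("P%02d", i)
    tr$session <- variant
    if (variant == "exp3") tr$count_base <- design$count_base
    tr
  }
  out <- dplyr::bind_rows(lapply(seq_len(design$n_participants),
                                 one_participant))
  finalize_trials(out)
}

finalize_trials <- function(trials) {
  trials$excluded <- FALSE
  trials$exclusion_reason <- NA_character_
  if (!"is_congruent" %in% names(trials)) trials$is_congruent <- NA
  core <- c("participant", "session", "sequence_index", "position", "rule",
            "is_switch", "is_congruent", "is_chunk_start", "rt_ms",
            "correct", "excluded", "exclusion_reason")
  extra <- setdiff(names(trials), core)
  trials[, c(core, extra)]
}

#' Simulate easy vs difficult 8-trial sequences
#'
#' Two sequence types, randomly interleaved within each participant.
#' Difficult sequences consist of rule-switch trials; they are chunked with
#' boundaries sampled from `dist` and RTs follow [simulate_rts()]. Easy
#' sequences consist only of rule-repeat trials and are executed under a
#' single program spanning all 8 trials: trial-1 RT has mean
#' `mu_base + kappa * 8` (the cost of assembling the larger program), and
#' trial `t > 1` has mean `mu_base + lambda * (8 - t)` — the load of the
#' maintained program decays as trials are completed, so easy-position means
#' decrease across the sequence. Under the defaults the expected easy
#' trial-1 mean (1050 ms) exceeds the expected difficult trial-1 mean
#' (1030 ms): it paradoxically takes longer to begin an easy sequence.
#'
#' @param params An [rt_model_params()].
#' @param dist Chunk-size distribution for difficult sequences.
#' @param n_participants,n_sequences Run size (defaults 23 participants, 250
#'   sequences each).
#' @param easy_fraction Probability a sequence is easy.
#' @param seed Integer seed.
#' @return A trial-record tibble as in [simulate_experiment()], with an
#'   extra `difficulty` column.
#' @examples
#' trials <- simulate_exp4(n_participants = 2, n_sequences = 20, seed = 1)
#' table(trials$difficulty) / 8
#' @export
simulate_exp4 <- function(params = rt_model_params(),
                          dist = chunk_dist_uniform(2, 6),
                          n_participants = 23, n_sequences = 250,
                          easy_fraction = 0.5, seed = 1) {
  stopifnot(inherits(params, "rt_model_params"))
  if (!is.null(dist)) dist <- chunk_dist_from_list(dist)
  len <- 8L
  rules <- c("value", "font")

  one_participant <- function(i) {
    set.seed(participant_seed(seed, i))
    easy <- stats::runif(n_sequences) < easy_fraction
    shift <- if (params$sd_participant > 0)
      stats::rnorm(1, 0, params$sd_participant) else 0

    seq_tables <- lapply(seq_len(n_sequences), function(s) {
      pos <- seq_len(len)
      if (easy[s]) {
        rule <- rep(rules[sample.int(2L, 1L)], len)
        starts <- c(TRUE, rep(FALSE, len - 1L))
        mu <- params$mu_base + shift +
          c(params$span_cost_per_trial * len,
            params$load_cost_per_remaining_trial * (len - pos[-1L]))
        sd <- c(params$sd_inst, rep(params$sd_base, len - 1L))
        rt <- pmax(stats::rnorm(len, mu, sd), params$rt_floor)
        correct <- stats::runif(len) >= params$err_base
        tibble::tibble(sequence_index = s, position = pos, rule = rule,
                       is_chunk_start = starts, rt_ms = rt,
                       correct = correct, difficulty = "easy")
      } else {
        start <- sample.int(2L, 1L) - 1L
        rule <- rules[(start + pos) %% 2L + 1L]
        f <- logical(len)
        f[sample_partition(len, dist)$start_positions] <- TRUE
        tibble::tibble(sequence_index = s, position = pos, rule = rule,
                       is_chunk_start = f, difficulty = "difficult")
      }
    })
    tr <- dplyr::bind_rows(seq_tables)
    n <- nrow(tr)
    tr$is_switch <- c(NA, tr$rule[-1L] != tr$rule[-n])

    hard <- tr$difficulty == "difficult"
    if (any(hard)) {
      sim <- simulate_rts(tr[hard, ], params, mu_shift = shift)
      tr$rt_ms[hard] <- sim$rt_ms
      tr$correct[hard] <- sim$correct
    }
    tr$participant <- sprintf("P%02d", i)
    tr$session <- "exp4"
    tr
  }
  out <- dplyr::bind_rows(lapply(seq_len(n_participants), one_participant))
  finalize_trials(out)
}

#' Correct answer to the end-of-sequence counting probe
#'
#' Participants covertly count trials in threes (1,2,3,1,2,3,...) or fives;
#' the probe asks for the count on the trial the sequence stopped at, i.e.
#' `((n_trials - 1) mod count_base) + 1`. A sequence counted in fives and
#' stopped after 18 trials has answer 3 (12345 12345 12345 123).
#'
#' @param count_base Counting base, 3 or 5.
#' @param n_trials Number of trials executed, >= 1.
#' @return Integer in `1..count_base`.
#' @examples
#' probe_answer(5, 18) # 3
#' probe_answer(3, 10) # 1
#' @export
probe_answer <- function(count_base, n_trials) {
  if (length(count_base) != 1L || !count_base %in% c(3, 5)) {
    stop("`count_base` must be 3 or 5", call. = FALSE)
  }
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials < 1 ||
      n_trials != as.integer(n_trials)) {
    stop("`n_trials` must be a positive integer", call. = FALSE)
  }
  as.integer((n_trials - 1) %% count_base + 1)
}

#' Cost-free chunking-scenario simulation (the illustration run)
#'
#' Simulates 10-trial sequences with no switch or congruency costs under one
#' of the named chunking regimes (see [chunk_dist_preset()]):
#' `"single_program"` forces chunk starts only at position 1; `"fixed3"`
#' yields RT peaks exactly at positions 1, 4, 7 and 10; the uniform regimes
#' yield increasingly smooth, gradually rising profiles. Defaults are 16
#' participants with 400 sequences each.
#'
#' @param scenario One of [chunking_presets()].
#' @param n_participants,n_sequences Run size.
#' @param sequence_length Trials per sequence.
#' @param params An [rt_model_params()].
#' @param seed Integer seed.
#' @param return `"profile"` (per-position across-participant means with
#'   t-based 95% CI half-widths), `"participant_means"` (participants x
#'   positions matrix of mean RTs), or `"trials"` (the full trial table with
#'   latent `is_chunk_start` truth).
#' @return See `return`.
#' @examples
#' simulate_figure2("fixed3", n_participants = 4, n_sequences = 50, seed = 1)
#' @export
simulate_figure2 <- function(scenario = "u2_9", n_participants = 16,
                             n_sequences = 400, sequence_length = 10,
                             params = rt_model_params(), seed = 1,
                             return = c("profile", "participant_means",
                                        "trials")) {
  return <- match.arg(return)
  if (!scenario %in% chunking_presets()) {
    stop("unknown scenario: ", scenario, "; see chunking_presets()",
         call. = FALSE)
  }
  dist <- chunk_dist_preset(scenario)
  len <- as.integer(sequence_length)
  lengths <- rep.int(len, n_sequences)

  sim_one <- function(i) {
    set.seed(participant_seed(seed, i))
    starts <- chunk_start_flags(lengths, dist)
    shift <- if (params$sd_participant > 0)
      stats::rnorm(1, 0, params$sd_participant) else 0
    mu <- ifelse(starts, params$mu_inst, params$mu_base) + shift
    sd <- ifelse(starts, params$sd_inst, params$sd_base)
    rt <- pmax(stats::rnorm(length(starts), mu, sd), params$rt_floor)
    list(starts = starts, rt = rt)
  }
  sims <- lapply(seq_len(n_participants), sim_one)
  position <- rep.int(seq_len(len), n_sequences)

  if (return == "trials") {
    tabs <- lapply(seq_along(sims), function(i) {
      tibble::tibble(participant = sprintf("P%02d", i),
                     session = paste0("figure2_", scenario),
                     sequence_index = rep.int(seq_len(n_sequences), lengths),
                     position = position, rule = "none",
                     is_switch = FALSE, is_congruent = NA,
                     is_chunk_start = sims[[i]]$starts,
                     rt_ms = sims[[i]]$rt, correct = TRUE)
    })
    return(finalize_trials(dplyr::bind_rows(tabs)))
  }

  m <- t(vapply(sims, function(s) {
    as.numeric(rowsum(s$rt, position)) / n_sequences
  }, numeric(len)))
  colnames(m) <- seq_len(len)
  rownames(m) <- sprintf("P%02d", seq_len(n_participants))
  if (return == "participant_means") {
    return(m)
  }
  profile_from_matrix(m)
}

# Across-participant profile from a participants x positions mean matrix.
profile_from_matrix <- function(m) {
  n <- nrow(m)
  ci <- if (n >= 2L) {
    stats::qt(0.975, n - 1L) * apply(m, 2L, stats::sd) / sqrt(n)
  } else {
    rep(NA_real_, ncol(m))
  }
  tibble::tibble(position = as.integer(colnames(m)),
                 mean_rt = colMeans(m),
                 ci_rt = as.numeric(ci),
                 n_participants = n)
}
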