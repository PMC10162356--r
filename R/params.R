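#' Generative reaction-time model parameters
#'
#' Parameters of the trial-level generative model. A trial that begins a
#' chunk (the site of a new program instantiation) draws its RT from
#' `Normal(mu_inst, sd_inst)`; any other trial draws from
#' `Normal(mu_base, sd_base)`. A rule-switch trial incurs `switch_cost`
#' unless it begins a chunk (switch costs are suppressed at chunk starts,
#' where the old program and its rule set have been dismantled); an
#' incongruent Stroop trial always incurs `stroop_cost` (congruency arises
#' within the current trial and is untouched by program boundaries). RTs are
#' clipped below at `rt_floor`. Accuracy is Bernoulli with error probability
#' `err_base`, plus `err_switch_increment` on switch trials; errors do not
#' depend on chunk-start status.
#'
#' Defaults: the instantiation distribution is 1030 +/- 46 ms and the
#' baseline distribution 850 +/- 27 ms (trial-1 vs within-program RTs of the
#' calibration experiment the simulation is built on). `switch_cost = 75` ms
#' is the midpoint of the reported 50-100 ms switch-cost range;
#' `stroop_cost = 150` ms the centre of the reported trial-1 congruency-cost
#' confidence interval [85, 210]. `span_cost_per_trial` (kappa) and
#' `load_cost_per_remaining_trial` (lambda) parameterize the
#' easy-sequence single-program model of [simulate_exp4()]: trial-1 RT grows
#' by kappa per trial of program span, and later trials carry lambda per
#' not-yet-executed trial (program load decays as the sequence is worked
#' through). kappa and lambda are free parameters of this package — only the
#' orderings they induce are empirically constrained. `sd_participant`
#' enables an optional hierarchical mode (participant-level mean offsets);
#' 0 disables it.
#'
#' @param mu_base,sd_base Baseline (within-program) RT mean and SD, ms.
#' @param mu_inst,sd_inst Program-instantiation RT mean and SD, ms.
#' @param switch_cost Added to non-chunk-start rule-switch trials, ms.
#' @param stroop_cost Added to incongruent Stroop trials, ms.
#' @param err_base Baseline error probability.
#' @param err_switch_increment Extra error probability on switch trials.
#' @param rt_floor Lower clip for simulated RTs, ms.
#' @param span_cost_per_trial kappa: trial-1 cost per trial of program span
#'   (easy sequences), ms.
#' @param load_cost_per_remaining_trial lambda: cost per remaining trial of
#'   the maintained program (easy sequences, trials > 1), ms.
#' @param sd_participant SD of participant-level mean offsets, ms (0 = single
#'   -level model, the default).
#' @return An object of class `rt_model_params`.
#' @examples
#' rt_model_params()
#' rt_model_params(switch_cost = 100)
#' @export
rt_model_params <- function(mu_base = 850, sd_base = 27,
                            mu_inst = 1030, sd_inst = 46,
                            switch_cost = 75, stroop_cost = 150,
                            err_base = 0.05, err_switch_increment = 0.05,
                            rt_floor = 150,
                            span_cost_per_trial = 25,
                            load_cost_per_remaining_trial = 8,
                            sd_participant = 0) {
  p <- list(mu_base = mu_base, sd_base = sd_base,
            mu_inst = mu_inst, sd_inst = sd_inst,
            switch_cost = switch_cost, stroop_cost = stroop_cost,
            err_base = err_base, err_switch_increment = err_switch_increment,
            rt_floor = rt_floor,
            span_cost_per_trial = span_cost_per_trial,
            load_cost_per_remaining_trial = load_cost_per_remaining_trial,
            sd_participant = sd_participant)
  if (p$sd_base <= 0 || p$sd_inst <= 0) {
    stop("RT standard deviations must be > 0", call. = FALSE)
  }
  if (p$err_base < 0 || p$err_base > 1 ||
      p$err_switch_increment < 0 || p$err_switch_increment > 1 ||
      p$err_base + p$err_switch_increment > 1) {
    stop("error probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p$rt_floor < 0) stop("`rt_floor` must be >= 0", call. = FALSE)
  if (p$sd_participant < 0) {
    stop("`sd_participant` must be >= 0", call. = FALSE)
  }
  structure(p, class = "rt_model_params")
}

#' @export
print.rt_model_params <- function(x, ...) {
  cat("<rt_model_params>\n")
  cat(sprintf("  baseline:       %g +/- %g ms\n", x$mu_base, x$sd_base))
  cat(sprintf("  instantiation:  %g +/- %g ms\n", x$mu_inst, x$sd_inst))
  cat(sprintf("  switch cost:    %g ms (suppressed at chunk starts)\n",
              x$switch_cost))
  cat(sprintf("  stroop cost:    %g ms\n", x$stroop_cost))
  cat(sprintf("  errors:         %g base + %g on switches\n",
              x$err_base, x$err_switch_increment))
  cat(sprintf("  exp4: kappa = %g, lambda = %g ms\n",
              x$span_cost_per_trial, x$load_cost_per_remaining_trial))
  invisible(x)
}

#' Experiment designs
#'
#' Describes one of the five synthetic experiment structures. Defaults match
#' the study conditions: 10-trial rule-switch or Stroop sequences with 16
#' participants and 250 sequences each (switch probability 0.5; exactly 70%
#' congruent Stroop trials); 15-trial strictly alternating sequences with 7
#' participants and 300 sequences (rules alternate every trial, the trial-1
#' rule alternating across sequences); 10-20-trial covert-counting sequences
#' with 31 participants and 80 sequences; and 8-trial easy (all-repeat) vs
#' difficult (all-switch) sequences with 23 participants and 250 sequences.
#' Inter-trial intervals (0.5 s within a sequence, 2 s across boundaries)
#' are carried as metadata only.
#'
#' @param variant One of `"exp1_switch"`, `"exp1_stroop"`, `"exp2"`,
#'   `"exp3"`, `"exp4"`.
#' @param n_participants,n_sequences Override the per-variant defaults.
#' @param switch_probability Per-transition switch probability for
#'   `exp1_switch`/`exp3` style rule sequences.
#' @param congruent_fraction Fraction of congruent trials per Stroop
#'   sequence (allocated exactly, per sequence).
#' @param count_base Covert counting base for `exp3`, 3 or 5.
#' @param easy_fraction Fraction of easy sequences for `exp4`.
#' @param dist Chunk-size distribution governing latent chunking; default
#'   uniform(2, 9) for spontaneous regimes, `fixed(count_base)` for `exp3`,
#'   uniform(2, 6) for `exp4` difficult sequences.
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design("exp1_switch")
#' experiment_design("exp3", count_base = 5)
#' @export
experiment_design <- function(variant = c("exp1_switch", "exp1_stroop",
                                          "exp2", "exp3", "exp4"),
                              n_participants = NULL, n_sequences = NULL,
                              switch_probability = 0.5,
                              congruent_fraction = 0.7,
                              count_base = 3, easy_fraction = 0.5,
                              dist = NULL) {
  variant <- match.arg(variant)
  defaults <- switch(variant,
    exp1_switch = list(len = 10L, n_part = 16L, n_seq = 250L,
                       dist = chunk_dist_uniform(2, 9)),
    exp1_stroop = list(len = 10L, n_part = 16L, n_seq = 250L,
                       dist = chunk_dist_uniform(2, 9)),
    exp2 = list(len = 15L, n_part = 7L, n_seq = 300L,
                dist = chunk_dist_uniform(2, 9)),
    exp3 = list(len = c(10L, 20L), n_part = 31L, n_seq = 80L,
                dist = NULL),
    exp4 = list(len = 8L, n_part = 23L, n_seq = 250L,
                dist = chunk_dist_uniform(2, 6))
  )
  if (variant == "exp3") {
    if (!count_base %in% c(3, 5)) {
      stop("`count_base` must be 3 or 5", call. = FALSE)
    }
    defaults$dist <- chunk_dist_fixed(count_base)
  }
  if (switch_probability < 0 || switch_probability > 1 ||
      congruent_fraction < 0 || congruent_fraction > 1 ||
      easy_fraction < 0 || easy_fraction > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    variant = variant,
    sequence_length = defaults$len,
    n_participants = as.integer(n_participants %||% defaults$n_part),
    n_sequences = as.integer(n_sequences %||% defaults$n_seq),
    switch_probability = switch_probability,
    congruent_fraction = congruent_fraction,
    count_base = if (variant == "exp3") as.integer(count_base) else NULL,
    easy_fraction = if (variant == "exp4") easy_fraction else NULL,
    dist = if (is.null(dist)) defaults$dist else chunk_dist_from_list(dist),
    iti_within_s = 0.5,
    iti_between_s = 2.0
  ), class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>", x$variant, "\n")
  cat("  sequence length:", paste(x$sequence_length, collapse = "-"), "\n")
  cat("  participants:", x$n_participants,
      " sequences:", x$n_sequences, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-participant RNG substream: adding participants to a run
# never reshuffles earlier participants.
participant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 + 1000003 * i) %% 2147483647)
}
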