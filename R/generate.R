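#' Generate per-trial rule labels with switch flags
#'
#' Builds one participant-session of rule labels under the design's regime.
#' `exp1_switch` and `exp3`: every transition (including across sequence
#' boundaries) is a switch independently with `switch_probability`. `exp2`:
#' rules alternate strictly within each sequence and the trial-1 rule
#' alternates across sequences, so both rules appear equally often at every
#' position. `exp4`: easy sequences are all-repeat (one rule per sequence);
#' difficult sequences alternate strictly.
#'
#' A trial's `is_switch` compares its rule with the immediately preceding
#' trial, including across the sequence boundary; the very first trial of
#' the session has no predecessor and gets `NA`.
#'
#' Randomness comes from the ambient RNG stream; seed it with [set.seed()]
#' (the simulate_* drivers do this per participant).
#'
#' @param design An [experiment_design()].
#' @param difficulty For `exp4` only: `"easy"` or `"difficult"`.
#' @return A [tibble::tibble()] with columns `sequence_index`, `position`,
#'   `rule`, `is_switch`.
#' @examples
#' set.seed(1)
#' generate_rule_sequence(experiment_design("exp2", n_sequences = 2))
#' @export
generate_rule_sequence <- function(design, difficulty = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  rules <- c("value", "font")
  v <- design$variant
  if (v == "exp1_stroop") {
    stop("rule sequences are not defined for the Stroop session; ",
         "use generate_stroop_trials()", call. = FALSE)
  }

  lengths <- sequence_lengths(design)
  n_seq <- design$n_sequences
  seq_index <- rep.int(seq_len(n_seq), lengths)
  position <- unlist(lapply(lengths, seq_len), use.names = FALSE)
  n <- length(position)

  rule <- switch(v,
    exp1_switch = ,
    exp3 = {
      sw <- c(FALSE, stats::runif(n - 1) < design$switch_probability)
      rules[(cumsum(sw) + (sample.int(2L, 1L) - 1L)) %% 2L + 1L]
    },
    exp2 = {
      # Alternation within and across sequences: rule index depends only on
      # the parity of sequence number + position.
      rules[(seq_index + position) %% 2L + 1L]
    },
    exp4 = {
      difficulty <- match.arg(difficulty, c("easy", "difficult"))
      if (difficulty == "easy") {
        per_seq <- rules[sample.int(2L, n_seq, replace = TRUE)]
        per_seq[seq_index]
      } else {
        start <- sample.int(2L, n_seq, replace = TRUE) - 1L
        rules[(start[seq_index] + position) %% 2L + 1L]
      }
    },
    stop("unknown variant: ", v, call. = FALSE)
  )

  is_switch <- c(NA, rule[-1L] != rule[-n])
  tibble::tibble(sequence_index = seq_index, position = position,
                 rule = rule, is_switch = is_switch)
}

sequence_lengths <- function(design) {
  len <- design$sequence_length
  if (length(len) == 2L) {
    # exp3: lengths unpredictable, uniform on the range.
    len[1L] + sample.int(len[2L] - len[1L] + 1L, design$n_sequences,
                         replace = TRUE) - 1L
  } else {
    rep.int(len, design$n_sequences)
  }
}

#' Generate Stroop trials with stratified congruency
#'
#' Builds one participant-session of Stroop trials: each sequence gets
#' exactly `round(congruent_fraction * length)` congruent trials (7 of 10
#' under the defaults) at randomized positions. The stimulus is a color word
#' drawn from Red/Blue/Green/White; on congruent trials it is printed in its
#' own color and the incorrect response option is a random other color, on
#' incongruent trials it is printed in a different color and the incorrect
#' option always repeats the stimulus word.
#'
#' @param design An [experiment_design()] with variant `"exp1_stroop"`.
#' @return A [tibble::tibble()] with columns `sequence_index`, `position`,
#'   `rule`, `is_switch`, `word`, `font_color`, `distractor`,
#'   `is_congruent`.
#' @examples
#' set.seed(1)
#' generate_stroop_trials(experiment_design("exp1_stroop", n_sequences = 2))
#' @export
generate_stroop_trials <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (design$variant != "exp1_stroop") {
    stop("`design` must have variant \"exp1_stroop\"", call. = FALSE)
  }
  words <- c("Red", "Blue", "Green", "White")
  len <- design$sequence_length
  n_seq <- design$n_sequences
  n_con <- as.integer(round(design$congruent_fraction * len))

  one_sequence <- function(s) {
    congruent <- logical(len)
    congruent[sample.int(len, n_con)] <- TRUE
    word <- words[sample.int(4L, len, replace = TRUE)]
    font <- word
    distractor <- character(len)
    for (i in seq_len(len)) {
      others <- words[words != word[i]]
      if (congruent[i]) {
        distractor[i] <- others[sample.int(3L, 1L)]
      } else {
        font[i] <- others[sample.int(3L, 1L)]
        distractor[i] <- word[i] # incorrect option repeats the stimulus word
      }
    }
    tibble::tibble(sequence_index = s, position = seq_len(len),
                   rule = "stroop-color", is_switch = FALSE,
                   word = word, font_color = font, distractor = distractor,
                   is_congruent = congruent)
  }

  out <- dplyr::bind_rows(lapply(seq_len(n_seq), one_sequence))
  out$is_switch[1L] <- NA
  out
}

#' Assign latent chunk-start flags to sequences
#'
#' For each sequence (grouped by `sequence_index`), samples a partition from
#' `dist` and flags the first trial of every chunk. With `dist = NULL`
#' (single-program regime) only position 1 of each sequence is flagged.
#'
#' @param trials A trial table with `sequence_index` and `position` columns
#'   (one participant-session, positions 1..L per sequence).
#' @param dist A [chunk_dist()] or `NULL`.
#' @return `trials` with a logical `is_chunk_start` column.
#' @export
assign_chunk_starts <- function(trials, dist = NULL) {
  lengths <- tabulate_lengths(trials)
  trials$is_chunk_start <- chunk_start_flags(lengths, dist)
  trials
}

tabulate_lengths <- function(trials) {
  idx <- trials$sequence_index
  as.integer(tabulate(match(idx, unique(idx))))
}

# One logical vector covering all sequences, TRUE where a chunk begins.
chunk_start_flags <- function(lengths, dist = NULL) {
  if (is.null(dist)) {
    flags <- logical(sum(lengths))
    flags[1L + c(0L, cumsum(lengths[-length(lengths)]))] <- TRUE
    return(flags)
  }
  unlist(lapply(lengths, function(L) {
    f <- logical(L)
    f[sample_partition(L, dist)$start_positions] <- TRUE
    f
  }), use.names = FALSE)
}
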