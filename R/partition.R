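#' Sequence partitions into consecutive chunks
#'
#' A partition is one realized division of an `n_trials`-long sequence into
#' consecutive chunks. Chunk sizes are drawn i.i.d. from the chunk-size
#' distribution until the sequence is filled; a draw overshooting the
#' remaining trials is truncated to the remainder, so the final chunk may be
#' shorter than any size in the support. Under this rule chunk-start
#' positions form an exact renewal process (truncation can only shorten the
#' last chunk, never move a start).
#'
#' @param n_trials Sequence length, a positive integer.
#' @param dist A [chunk_dist()].
#' @return `sample_partition()` returns an object of class `chunk_partition`
#'   with elements `n_trials`, `sizes` and `start_positions` (1-based trial
#'   indices at which chunks begin).
#' @examples
#' set.seed(1)
#' sample_partition(10, chunk_dist_uniform(2, 9))
#' sample_partition(10, chunk_dist_fixed(3)) # always [3, 3, 3, 1]
#' @export
sample_partition <- function(n_trials, dist) {
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials < 1 ||
      n_trials != as.integer(n_trials)) {
    stop("`n_trials` must be a positive integer", call. = FALSE)
  }
  stopifnot(inherits(dist, "chunk_dist"))
  n_trials <- as.integer(n_trials)
  # Enough i.i.d. draws to cover the sequence even if every draw is minimal.
  k <- ceiling(n_trials / min(dist$sizes))
  draws <- dist$sizes[sample.int(length(dist$sizes), k, replace = TRUE,
                                 prob = dist$probs)]
  cs <- cumsum(draws)
  j <- which(cs >= n_trials)[1L]
  sizes <- draws[seq_len(j)]
  sizes[j] <- n_trials - (cs[j] - draws[j])
  new_partition(n_trials, sizes)
}

new_partition <- function(n_trials, sizes) {
  sizes <- as.integer(sizes)
  if (sum(sizes) != n_trials) {
    stop("partition sizes must sum to n_trials", call. = FALSE)
  }
  starts <- 1L + c(0L, cumsum(sizes[-length(sizes)]))
  structure(list(n_trials = as.integer(n_trials), sizes = sizes,
                 start_positions = as.integer(starts)),
            class = "chunk_partition")
}

#' @export
print.chunk_partition <- function(x, ...) {
  cat("<chunk_partition>", x$n_trials, "trials\n")
  cat("  sizes: ", paste(x$sizes, collapse = " "), "\n")
  cat("  starts:", paste(x$start_positions, collapse = " "), "\n")
  invisible(x)
}

#' Exhaustively enumerate partitions and their probabilities
#'
#' Brute-force oracle for [sample_partition()] and [start_probabilities()]:
#' lists every partition reachable under the truncation rule together with
#' its exact probability. Draws that overshoot the remainder are merged,
#' since they all truncate to the same final chunk.
#'
#' @inheritParams sample_partition
#' @param cap Refuse enumeration above this sequence length (combinatorial
#'   growth; the oracle is only needed at small `n_trials`).
#' @return A [tibble::tibble()] with a list-column `sizes` and a numeric
#'   column `prob`; probabilities sum to 1 within 1e-12.
#' @examples
#' enumerate_partitions(4, chunk_dist_uniform(2, 3))
#' @export
enumerate_partitions <- function(n_trials, dist, cap = 15L) {
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials < 1 ||
      n_trials != as.integer(n_trials)) {
    stop("`n_trials` must be a positive integer", call. = FALSE)
  }
  if (n_trials > cap) {
    stop("refusing to enumerate partitions for n_trials = ", n_trials,
         " (cap = ", cap, "); raise `cap` deliberately if needed",
         call. = FALSE)
  }
  stopifnot(inherits(dist, "chunk_dist"))

  recurse <- function(remaining) {
    out <- list()
    inner <- dist$sizes < remaining
    for (i in which(inner)) {
      s <- dist$sizes[i]
      for (sub in recurse(remaining - s)) {
        out[[length(out) + 1L]] <- list(sizes = c(s, sub$sizes),
                                        prob = dist$probs[i] * sub$prob)
      }
    }
    # Any draw >= remaining ends the sequence with a (possibly truncated)
    # final chunk of exactly `remaining` trials.
    p_final <- sum(dist$probs[!inner])
    if (p_final > 0) {
      out[[length(out) + 1L]] <- list(sizes = remaining, prob = p_final)
    }
    out
  }

  parts <- recurse(as.integer(n_trials))
  tibble::tibble(
    sizes = lapply(parts, function(p) as.integer(p$sizes)),
    prob = vapply(parts, function(p) p$prob, numeric(1))
  )
}

#' Per-position chunk-start probabilities (renewal recursion)
#'
#' Computes, for each 1-based trial position `t` of an `n_trials` sequence,
#' the probability that `t` begins a new chunk, i.e. is the site of a new
#' program instantiation. Trial 1 always starts a chunk. For `t > 1` the
#' renewal recursion is `p[t] = sum over sizes s with t - s >= 1 of
#' P(s) * p[t - s]`: a start at `t` requires the previous chunk to have
#' started at `t - s` and run its full drawn length `s`. Truncation only
#' shortens the final chunk past the end of the sequence, so it never
#' affects start positions and the recursion is exact.
#'
#' @inheritParams sample_partition
#' @return An object of class `start_prob_profile`: a list with `n_trials`
#'   and numeric `p` of length `n_trials`, `p[1] == 1`.
#' @examples
#' start_probabilities(10, chunk_dist_fixed(3))$p # 1 0 0 1 0 0 1 0 0 1
#' start_probabilities(4, chunk_dist_uniform(2, 3))$p # 1 0 0.5 0.5
#' @export
start_probabilities <- function(n_trials, dist) {
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials < 1 ||
      n_trials != as.integer(n_trials)) {
    stop("`n_trials` must be a positive integer", call. = FALSE)
  }
  stopifnot(inherits(dist, "chunk_dist"))
  n <- as.integer(n_trials)
  p <- numeric(n)
  p[1L] <- 1
  if (n > 1L) {
    for (t in 2:n) {
      prev <- t - dist$sizes
      ok <- prev >= 1L
      if (any(ok)) {
        p[t] <- sum(dist$probs[ok] * p[prev[ok]])
      }
    }
  }
  structure(list(n_trials = n, p = p), class = "start_prob_profile")
}

#' @export
print.start_prob_profile <- function(x, ...) {
  cat("<start_prob_profile>", x$n_trials, "trials\n")
  print(round(x$p, 4))
  invisible(x)
}

#' Closed-form expected RT per trial position
#'
#' Under the cost-free generative model, a trial's RT is drawn from the
#' program-instantiation distribution when it starts a chunk and from the
#' baseline distribution otherwise, so the expected mean RT at position `t`
#' is `p[t] * mu_inst + (1 - p[t]) * mu_base`. Monte-Carlo position means
#' from the simulator converge to these values.
#'
#' @param profile A [start_probabilities()] result (or a bare numeric vector
#'   of chunk-start probabilities).
#' @param params An [rt_model_params()] object.
#' @return Numeric vector of expected mean RTs (ms), one per position.
#' @examples
#' expected_position_rt(start_probabilities(10, chunk_dist_fixed(3)),
#'                      rt_model_params())
#' @export
expected_position_rt <- function(profile, params = rt_model_params()) {
  p <- if (inherits(profile, "start_prob_profile")) profile$p else
    as.numeric(profile)
  if (any(p < 0 | p > 1)) {
    stop("chunk-start probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(params, "rt_model_params"))
  p * params$mu_inst + (1 - p) * params$mu_base
}
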