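# Shared fixtures and independent oracles for the suite.

# Marginal chunk-start probabilities folded from the exhaustive enumeration
# (independent of the renewal recursion).
start_marginals_from_enumeration <- function(n, dist) {
  en <- enumerate_partitions(n, dist)
  p <- numeric(n)
  for (i in seq_len(nrow(en))) {
    sizes <- en$sizes[[i]]
    starts <- 1L + c(0L, cumsum(sizes[-length(sizes)]))
    p[starts] <- p[starts] + en$prob[i]
  }
  p
}

oracle_dists <- function() {
  list(fixed3 = chunk_dist_fixed(3),
       fixed5 = chunk_dist_fixed(5),
       u2_3 = chunk_dist_uniform(2, 3),
       u3_5 = chunk_dist_uniform(3, 5),
       u2_6 = chunk_dist_uniform(2, 6))
}

# A constant-RT, all-correct trial table: n_seq sequences of len trials for
# each participant/session combination.
constant_trials <- function(participants = "P01", sessions = "s1",
                            n_seq = 7, len = 10, rt = 850) {
  grid <- expand.grid(position = seq_len(len),
                      sequence_index = seq_len(n_seq),
                      session = sessions,
                      participant = participants,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    participant = grid$participant, session = grid$session,
    sequence_index = grid$sequence_index, position = grid$position,
    rule = "value", is_switch = FALSE, is_congruent = NA,
    is_chunk_start = grid$position == 1L,
    rt_ms = rt, correct = TRUE
  )
}
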