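#' Chunk-size distributions
#'
#' A `chunk_dist` is a probability mass function over admissible chunk
#' lengths (in trials). It drives both the partition sampler
#' ([sample_partition()]) and the analytic renewal recursion
#' ([start_probabilities()]). Chunk sizes of 1 trial are admissible in the
#' support only if supplied explicitly; a 1-trial final chunk can always
#' arise through truncation (see [sample_partition()]).
#'
#' @param sizes Strictly increasing vector of positive integer chunk lengths.
#' @param probs Matching vector of probabilities (non-negative, summing to 1
#'   within 1e-9).
#' @param kind Internal tag used for serialization; one of `"pmf"`,
#'   `"fixed"`, `"uniform"`.
#' @return An object of class `chunk_dist` with elements `sizes`, `probs`,
#'   `kind`.
#' @examples
#' chunk_dist_fixed(3)
#' chunk_dist_uniform(2, 9)
#' chunk_dist(c(2, 5), c(0.3, 0.7))
#' @export
chunk_dist <- function(sizes, probs, kind = "pmf") {
  if (length(sizes) < 1L) {
    stop("`sizes` must contain at least one chunk length", call. = FALSE)
  }
  if (length(sizes) != length(probs)) {
    stop("`sizes` and `probs` must have the same length", call. = FALSE)
  }
  if (any(sizes != as.integer(sizes)) || any(sizes < 1)) {
    stop("chunk sizes must be positive integers", call. = FALSE)
  }
  sizes <- as.integer(sizes)
  if (length(sizes) > 1L && is.unsorted(sizes, strictly = TRUE)) {
    stop("`sizes` must be strictly increasing", call. = FALSE)
  }
  probs <- as.numeric(probs)
  if (any(probs < 0)) {
    stop("`probs` must be non-negative", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("`probs` must sum to 1 (within 1e-9)", call. = FALSE)
  }
  structure(list(sizes = sizes, probs = probs, kind = kind),
            class = "chunk_dist")
}

#' @rdname chunk_dist
#' @param k Fixed chunk length for the point-mass constructor.
#' @export
chunk_dist_fixed <- function(k) {
  chunk_dist(k, 1, kind = "fixed")
}

#' @rdname chunk_dist
#' @param a,b Lower and upper chunk lengths for the uniform constructor
#'   (equal probability on `a..b`).
#' @export
chunk_dist_uniform <- function(a, b) {
  if (length(a) != 1L || length(b) != 1L || a > b) {
    stop("`a` and `b` must be scalars with a <= b", call. = FALSE)
  }
  n <- b - a + 1L
  chunk_dist(seq.int(a, b), rep(1 / n, n), kind = "uniform")
}

#' @export
print.chunk_dist <- function(x, ...) {
  cat("<chunk_dist>", x$kind, "\n")
  cat("  sizes:", x$sizes, "\n")
  cat("  probs:", signif(x$probs, 4), "\n")
  invisible(x)
}

#' Expected chunk size E[S]
#'
#' @param dist A [chunk_dist()].
#' @return The mean of the chunk-size distribution, in trials.
#' @export
mean_chunk_size <- function(dist) {
  stopifnot(inherits(dist, "chunk_dist"))
  sum(dist$sizes * dist$probs)
}

#' Serialize / deserialize chunk-size distributions
#'
#' Round-trip a `chunk_dist` through the plain-list form used in run
#' configuration files: `{"kind": "fixed", "size": k}`,
#' `{"kind": "uniform", "min": a, "max": b}` or
#' `{"kind": "pmf", "sizes": [...], "probs": [...]}`.
#'
#' @param dist A [chunk_dist()].
#' @param x A list in one of the forms above.
#' @return `chunk_dist_to_list()` a plain list; `chunk_dist_from_list()` a
#'   `chunk_dist`.
#' @export
chunk_dist_to_list <- function(dist) {
  stopifnot(inherits(dist, "chunk_dist"))
  switch(dist$kind,
    fixed = list(kind = "fixed", size = dist$sizes[[1L]]),
    uniform = list(kind = "uniform",
                   min = dist$sizes[[1L]],
                   max = dist$sizes[[length(dist$sizes)]]),
    list(kind = "pmf", sizes = dist$sizes, probs = dist$probs)
  )
}

#' @rdname chunk_dist_to_list
#' @export
chunk_dist_from_list <- function(x) {
  if (inherits(x, "chunk_dist")) {
    return(x)
  }
  if (is.null(x$kind)) {
    stop("distribution spec needs a `kind` field", call. = FALSE)
  }
  switch(as.character(x$kind),
    fixed = chunk_dist_fixed(x$size),
    uniform = chunk_dist_uniform(x$min, x$max),
    pmf = chunk_dist(unlist(x$sizes), unlist(x$probs)),
    stop("unknown distribution kind: ", x$kind, call. = FALSE)
  )
}

#' Named chunking presets
#'
#' Shorthand for the chunking regimes used throughout: `"fixed3"` /
#' `"fixed5"` (constant 3- or 5-trial chunks, as under instructed counting),
#' `"u2_6"` and `"u2_9"` (variable chunks uniform on 2..6 / 2..9, the
#' spontaneous-chunking regimes), and the narrower `"u3_5"`, `"u3_6"`,
#' `"u3_9"` variants. `"single_program"` denotes the no-chunking regime
#' (one program spans the whole sequence) and maps to `NULL`.
#'
#' @param name Preset name.
#' @return A [chunk_dist()], or `NULL` for `"single_program"`.
#' @export
chunk_dist_preset <- function(name) {
  switch(name,
    single_program = NULL,
    fixed3 = chunk_dist_fixed(3),
    fixed5 = chunk_dist_fixed(5),
    u3_5 = chunk_dist_uniform(3, 5),
    u3_6 = chunk_dist_uniform(3, 6),
    u3_9 = chunk_dist_uniform(3, 9),
    u2_6 = chunk_dist_uniform(2, 6),
    u2_9 = chunk_dist_uniform(2, 9),
    stop("unknown chunking preset: ", name, call. = FALSE)
  )
}

#' @rdname chunk_dist_preset
#' @export
chunking_presets <- function() {
  c("single_program", "fixed3", "fixed5", "u3_5", "u3_6", "u3_9",
    "u2_6", "u2_9")
}
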