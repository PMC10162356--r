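#' Apply the standard exclusion rules to a trial table
#'
#' Three rules, applied in order on a fresh copy of the flags (so the
#' operation is idempotent):
#' \enumerate{
#'   \item \strong{Warmup}: the first 5 sequences of each
#'     participant-session are removed from all analyses (practice effects);
#'     implemented as 5 sequences rather than 50 trials so it is robust to
#'     sequence lengths other than 10.
#'   \item \strong{Errors}: incorrect post-warmup trials are excluded from
#'     RT aggregation but retained for error-rate aggregation.
#'   \item \strong{Outliers}: among the remaining trials, RTs farther than 5
#'     standard deviations from the participant's mean are flagged, in a
#'     single (non-iterative) pass. Mean and SD are computed per participant
#'     from post-warmup correct trials (set `include_errors = TRUE` to let
#'     error trials enter the statistics). Participants with zero RT spread
#'     get no outlier flags.
#' }
#'
#' @param trials Trial table with at least `participant`, `session`,
#'   `sequence_index`, `position`, `rt_ms`, `correct`.
#' @param n_warmup_sequences Number of initial sequences to drop per
#'   participant-session.
#' @param sd_limit Trimming threshold in participant SD units.
#' @param include_errors Whether error trials enter the trimming statistics.
#' @return A list with `trials` (annotated: `excluded`, `exclusion_reason`
#'   in `"warmup"`, `"error"`, `"outlier"` or `NA`) and `report` (an
#'   `exclusion_report`: input/removed counts and per-participant trimming
#'   thresholds).
#' @examples
#' trials <- simulate_experiment("exp1_switch", n_participants = 2,
#'                               n_sequences = 10, seed = 1)
#' res <- apply_exclusions(trials)
#' res$report
#' @export
apply_exclusions <- function(trials, n_warmup_sequences = 5,
                             sd_limit = 5, include_errors = FALSE) {
  required <- c("participant", "session", "sequence_index", "position",
                "rt_ms", "correct")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0L) {
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  n_input <- nrow(trials)
  reason <- rep(NA_character_, n_input)

  # 1. Warmup: first n sequences of each participant-session.
  cell <- paste(trials$participant, trials$session, sep = "\r")
  warmup <- logical(n_input)
  for (cl in unique(cell)) {
    idx <- cell == cl
    first_seqs <- sort(unique(trials$sequence_index[idx]))
    first_seqs <- first_seqs[seq_len(min(n_warmup_sequences,
                                         length(first_seqs)))]
    warmup[idx & trials$sequence_index %in% first_seqs] <- TRUE
  }
  reason[warmup] <- "warmup"

  # 2. Errors (post-warmup), excluded from RT but kept for error rates.
  err <- !warmup & !trials$correct
  reason[err] <- "error"

  # 3. Per-participant 5-SD trimming, single pass.
  stats_pool <- !warmup & (include_errors | trials$correct)
  thresholds <- lapply(split(seq_len(n_input), trials$participant),
                       function(idx) {
    pool <- idx[stats_pool[idx]]
    m <- mean(trials$rt_ms[pool])
    s <- stats::sd(trials$rt_ms[pool])
    if (is.na(s)) s <- 0
    list(mean = m, sd = s,
         lower = m - sd_limit * s, upper = m + sd_limit * s)
  })
  outlier <- logical(n_input)
  for (p in names(thresholds)) {
    th <- thresholds[[p]]
    if (th$sd == 0) next
    cand <- trials$participant == p & !warmup & trials$correct
    outlier[cand & (trials$rt_ms < th$lower | trials$rt_ms > th$upper)] <-
      TRUE
  }
  reason[outlier] <- "outlier"

  trials$excluded <- !is.na(reason)
  trials$exclusion_reason <- reason

  report <- structure(list(
    n_input = n_input,
    n_warmup_removed = sum(warmup),
    n_error_excluded = sum(err),
    n_outlier_excluded = sum(outlier),
    n_retained = sum(is.na(reason)),
    thresholds = tibble::tibble(
      participant = names(thresholds),
      mean_rt = vapply(thresholds, `[[`, numeric(1), "mean"),
      sd_rt = vapply(thresholds, `[[`, numeric(1), "sd"),
      lower = vapply(thresholds, `[[`, numeric(1), "lower"),
      upper = vapply(thresholds, `[[`, numeric(1), "upper")
    )
  ), class = "exclusion_report")

  list(trials = trials, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report>\n")
  cat(sprintf("  input trials:     %d\n", x$n_input))
  cat(sprintf("  warmup removed:   %d\n", x$n_warmup_removed))
  cat(sprintf("  error excluded:   %d (kept for error rates)\n",
              x$n_error_excluded))
  cat(sprintf("  outlier excluded: %d\n", x$n_outlier_excluded))
  cat(sprintf("  retained for RT:  %d\n", x$n_retained))
  invisible(x)
}

#' Write an exclusion report as JSON
#'
#' @param report An `exclusion_report` from [apply_exclusions()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  stopifnot(inherits(report, "exclusion_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
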