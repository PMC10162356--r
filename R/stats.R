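#' Per-position RT and error-rate profile
#'
#' Aggregates an (annotated) trial table into per-position means:
#' participant-level means are computed first, then the unweighted
#' across-participant mean with a t-based 95% confidence-interval half-width.
#' RTs use retained correct trials only (`excluded == FALSE`); error rates
#' use all non-warmup trials, so excluded error trials still count against
#' accuracy.
#'
#' @param trials Trial table; run [apply_exclusions()] first for the
#'   standard analysis chain (tables without exclusion flags are used as
#'   is).
#' @param split_by Optional character vector of condition columns (e.g.
#'   `"is_switch"`, `"is_congruent"`, `"difficulty"`) to profile separately.
#' @return A tibble with `split_by` columns, `position`, `mean_rt`, `ci_rt`,
#'   `mean_error`, `n_participants`. Participants contributing no retained
#'   trial to a cell are dropped from that cell with a warning.
#' @export
position_profile <- function(trials, split_by = NULL) {
  keys <- c("participant", split_by, "position")
  rt_rows <- retained_rt(trials)
  part <- rt_rows |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(rt = mean(.data$rt_ms), .groups = "drop")

  err_rows <- non_warmup(trials)
  part_err <- err_rows |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(err = mean(!.data$correct), .groups = "drop")
  part <- dplyr::full_join(part, part_err, by = keys)

  prof <- part |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(split_by, "position")))) |>
    dplyr::summarise(
      mean_rt = mean(.data$rt[!is.na(.data$rt)]),
      ci_rt = ci_halfwidth(.data$rt[!is.na(.data$rt)]),
      mean_error = mean(.data$err, na.rm = TRUE),
      n_participants = sum(!is.na(.data$rt)),
      .groups = "drop"
    )

  n_all <- length(unique(trials$participant))
  if (any(prof$n_participants < n_all)) {
    warning("some participants contribute no retained trial to one or more ",
            "cells; those cells use fewer participants", call. = FALSE)
  }
  prof
}

retained_rt <- function(trials) {
  keep <- trials$correct
  if ("excluded" %in% names(trials)) keep <- keep & !trials$excluded
  trials[keep, , drop = FALSE]
}

non_warmup <- function(trials) {
  if (!"exclusion_reason" %in% names(trials)) return(trials)
  keep <- is.na(trials$exclusion_reason) |
    trials$exclusion_reason != "warmup"
  trials[keep, , drop = FALSE]
}

ci_halfwidth <- function(x, conf_level = 0.95) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::qt(1 - (1 - conf_level) / 2, n - 1L) * stats::sd(x) / sqrt(n)
}

#' Participants-by-positions mean matrix
#'
#' Builds the complete-cell matrix most of the inferential functions take:
#' one row per participant, one column per position, entries are
#' participant-level mean RT (retained correct trials) or error rate
#' (non-warmup trials). Cells with no contributing trial are `NA`.
#'
#' @param trials Trial table (annotate with [apply_exclusions()] first).
#' @param positions Positions to keep (default: all present).
#' @param value `"rt"` or `"error"`.
#' @param subset Optional logical vector selecting rows of `trials` before
#'   aggregation (e.g. `trials$difficulty == "easy"`).
#' @return Numeric matrix with participant rownames and position colnames.
#' @export
position_means_matrix <- function(trials, positions = NULL,
                                  value = c("rt", "error"), subset = NULL) {
  value <- match.arg(value)
  if (!is.null(subset)) trials <- trials[subset, , drop = FALSE]
  rows <- if (value == "rt") retained_rt(trials) else non_warmup(trials)
  if (is.null(positions)) positions <- sort(unique(rows$position))
  rows <- rows[rows$position %in% positions, , drop = FALSE]
  y <- if (value == "rt") rows$rt_ms else as.numeric(!rows$correct)
  parts <- sort(unique(trials$participant))
  m <- matrix(NA_real_, length(parts), length(positions),
              dimnames = list(parts, positions))
  agg <- tapply(y, list(rows$participant, rows$position), mean)
  m[rownames(agg), colnames(agg)] <- agg
  m
}

#' Linear trend contrast over positions
#'
#' Tests for a linear trend of participant-level means across ordinal
#' positions: each participant's least-squares slope against centred,
#' equally spaced position codes is computed, then a two-sided one-sample t
#' test of the slopes against zero (df = participants - 1). Under complete
#' balanced data this is equivalent to the classical polynomial linear
#' contrast.
#'
#' @param position_means Participants x positions matrix (or data frame);
#'   column names are taken as position codes when numeric.
#' @return An object of class `contrast_result`: `slope_per_position` (mean
#'   slope, ms/position), `t`, `df`, `p`, and `participant_slopes`.
#' @export
linear_contrast <- function(position_means) {
  m <- as.matrix(position_means)
  if (nrow(m) < 2L) stop("need >= 2 participants", call. = FALSE)
  if (ncol(m) < 3L) stop("need >= 3 positions", call. = FALSE)
  if (anyNA(m)) stop("`position_means` has missing cells", call. = FALSE)
  x <- suppressWarnings(as.numeric(colnames(m)))
  if (anyNA(x)) x <- seq_len(ncol(m))
  xc <- x - mean(x)
  slopes <- as.numeric(m %*% xc) / sum(xc^2)
  n <- length(slopes)
  s <- stats::sd(slopes)
  if (s == 0) {
    if (all(slopes == 0)) {
      return(structure(list(slope_per_position = 0, t = 0, df = n - 1L,
                            p = 1, participant_slopes = slopes),
                       class = "contrast_result"))
    }
    stop("degenerate contrast: participant slopes are identical and ",
         "non-zero (zero between-participant variance)", call. = FALSE)
  }
  tval <- mean(slopes) / (s / sqrt(n))
  structure(list(
    slope_per_position = mean(slopes),
    t = tval, df = n - 1L,
    p = 2 * stats::pt(abs(tval), n - 1L, lower.tail = FALSE),
    participant_slopes = slopes
  ), class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> slope = %.3f ms/position, t(%d) = %.2f, p = %.4g\n",
              x$slope_per_position, x$df, x$t, x$p))
  invisible(x)
}

#' One-way repeated-measures ANOVA over positions
#'
#' Classical within-subject one-way RM-ANOVA with participant as block,
#' fitted via [stats::aov()] with an `Error(participant)` stratum; no
#' sphericity correction (`gg_correct = TRUE` applies Greenhouse-Geisser
#' epsilon to the degrees of freedom). Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param position_means Complete participants x positions matrix.
#' @param gg_correct Apply the Greenhouse-Geisser correction (off by
#'   default).
#' @return An object of class `anova_result`: `F`, `df_num`, `df_den`, `p`,
#'   `partial_eta_sq`, `ss_effect`, `ss_error`.
#' @export
rm_anova_oneway <- function(position_means, gg_correct = FALSE) {
  m <- as.matrix(position_means)
  if (ncol(m) < 2L) stop("need >= 2 positions", call. = FALSE)
  if (nrow(m) < 2L) stop("need >= 2 participants", call. = FALSE)
  if (anyNA(m)) stop("`position_means` has missing cells", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  long <- data.frame(
    y = as.numeric(m),
    position = factor(rep(seq_len(k), each = n)),
    participant = factor(rep(seq_len(n), times = k))
  )
  fit <- stats::aov(y ~ position + Error(participant), data = long)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  ss_pos <- tab["position", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  df_num <- k - 1L
  df_den <- (k - 1L) * (n - 1L)
  # guard against pure floating-point residue in degenerate (constant) data
  scale <- max(mean(m^2), 1)
  if (ss_pos < 1e-10 * scale) ss_pos <- 0
  if (ss_err < 1e-10 * scale) ss_err <- 0
  if (ss_pos == 0) {
    fval <- 0
    pval <- 1
  } else if (ss_err == 0) {
    fval <- Inf
    pval <- 0
  } else {
    fval <- (ss_pos / df_num) / (ss_err / df_den)
    pval <- stats::pf(fval, df_num, df_den, lower.tail = FALSE)
  }
  eps <- 1
  if (gg_correct && is.finite(fval) && fval > 0) {
    eps <- gg_epsilon(m)
    pval <- stats::pf(fval, eps * df_num, eps * df_den, lower.tail = FALSE)
  }
  structure(list(
    F = fval, df_num = df_num, df_den = df_den, p = pval,
    partial_eta_sq = if (ss_pos + ss_err > 0) ss_pos / (ss_pos + ss_err)
      else 0,
    ss_effect = ss_pos, ss_error = ss_err, gg_epsilon = eps
  ), class = "anova_result")
}

# Greenhouse-Geisser epsilon from the sample covariance of the columns.
gg_epsilon <- function(m) {
  S <- stats::cov(m)
  k <- ncol(S)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.2f, p = %.4g, partial eta^2 = %.3f\n",
              x$df_num, x$df_den, x$F, x$p, x$partial_eta_sq))
  invisible(x)
}

#' Switch- or Stroop-cost trajectory across positions
#'
#' For each participant and position, the cost is the mean RT difference
#' between condition levels: switch minus repeat trials (`"switch"`) or
#' incongruent minus congruent trials (`"stroop"`), on retained correct
#' trials. Positions where any participant lacks one of the two levels are
#' dropped (with a warning) so the trend test runs on a complete matrix.
#'
#' @param trials Annotated trial table.
#' @param cost_kind `"switch"` or `"stroop"`.
#' @param positions Analysis window (default 2 up to the maximum position,
#'   since position 1 of a sequence is analysed separately).
#' @return A list of class `cost_profile`: `profile` (per-position mean cost
#'   with 95% CI half-width), `contrast` (a [linear_contrast()] over the
#'   cost matrix) and `matrix` (participants x positions costs).
#' @export
cost_profile <- function(trials, cost_kind = c("switch", "stroop"),
                         positions = NULL) {
  cost_kind <- match.arg(cost_kind)
  rows <- retained_rt(trials)
  cond <- switch(cost_kind,
    switch = rows[["is_switch"]],
    stroop = if ("is_congruent" %in% names(rows)) !rows[["is_congruent"]]
  )
  if (length(cond) == 0L || !any(cond %in% TRUE) || !any(cond %in% FALSE)) {
    stop("trial table carries no ", cost_kind, " condition labels ",
         "with both levels", call. = FALSE)
  }
  keep <- !is.na(cond)
  rows <- rows[keep, , drop = FALSE]
  cond <- cond[keep]
  if (is.null(positions)) positions <- 2:max(rows$position)
  rows_w <- rows$position %in% positions
  rows <- rows[rows_w, , drop = FALSE]
  cond <- cond[rows_w]

  hi <- tapply(rows$rt_ms[cond], list(rows$participant[cond],
                                      rows$position[cond]), mean)
  lo <- tapply(rows$rt_ms[!cond], list(rows$participant[!cond],
                                       rows$position[!cond]), mean)
  parts <- sort(unique(rows$participant))
  cost <- matrix(NA_real_, length(parts), length(positions),
                 dimnames = list(parts, positions))
  common_r <- intersect(rownames(hi), rownames(lo))
  common_c <- intersect(colnames(hi), colnames(lo))
  cost[common_r, common_c] <- hi[common_r, common_c] - lo[common_r, common_c]

  complete <- colSums(is.na(cost)) == 0L
  if (!all(complete)) {
    warning("dropping position(s) ",
            paste(colnames(cost)[!complete], collapse = ", "),
            ": some participants lack both ", cost_kind, " levels there",
            call. = FALSE)
    cost <- cost[, complete, drop = FALSE]
  }
  profile <- tibble::tibble(
    position = as.integer(colnames(cost)),
    mean_cost = colMeans(cost),
    ci_cost = apply(cost, 2L, ci_halfwidth),
    n_participants = nrow(cost)
  )
  structure(list(profile = profile,
                 contrast = linear_contrast(cost),
                 matrix = cost,
                 cost_kind = cost_kind),
            class = "cost_profile")
}

#' @export
print.cost_profile <- function(x, ...) {
  cat("<cost_profile>", x$cost_kind, "cost\n")
  print(x$profile)
  print(x$contrast)
  invisible(x)
}

#' Paired comparison of per-participant means
#'
#' Two-sided paired t test of `a` against `b`, with the 95% confidence
#' interval of the difference and, when a family of companion p-values is
#' supplied, the Holm step-down adjusted p-value of this comparison within
#' that family.
#'
#' @param a,b Equal-length numeric vectors of per-participant means.
#' @param family Optional numeric vector of the other p-values in the
#'   comparison family.
#' @param conf_level Confidence level for the interval.
#' @return A list of class `paired_comparison`: `mean_diff`, `t`, `df`, `p`,
#'   `conf_low`, `conf_high`, and `p_holm` (`NA` without a family).
#' @examples
#' paired_comparison(c(10, 20, 30), c(0, 0, 0))
#' @export
paired_comparison <- function(a, b, family = NULL, conf_level = 0.95) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length", call. = FALSE)
  }
  if (length(a) < 2L) stop("need >= 2 participants", call. = FALSE)
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      res <- list(mean_diff = 0, t = 0, df = n - 1L, p = 1,
                  conf_low = 0, conf_high = 0)
    } else {
      stop("degenerate comparison: all pairwise differences are identical ",
           "and non-zero", call. = FALSE)
    }
  } else {
    tt <- stats::t.test(a, b, paired = TRUE, conf.level = conf_level)
    res <- list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value,
                conf_low = tt$conf.int[1L], conf_high = tt$conf.int[2L])
  }
  res$p_holm <- if (is.null(family)) NA_real_ else
    stats::p.adjust(c(res$p, family), method = "holm")[1L]
  structure(res, class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> diff = %.2f, t(%d) = %.2f, p = %.4g, 95%% CI [%.2f, %.2f]\n",
              x$mean_diff, x$df, x$t, x$p, x$conf_low, x$conf_high))
  if (!is.na(x$p_holm)) cat(sprintf("  Holm-adjusted p = %.4g\n", x$p_holm))
  invisible(x)
}

#' Chunk-position vs non-chunk-position RT comparison
#'
#' For instructed-counting data with stride `s`, the chunk positions inside
#' the analysis window are `s + 1, 2s + 1, ...` (e.g. 4, 7, 10, 13 for
#' 3-counting and 6, 11 for 5-counting in a 2..15 window). Each
#' participant's mean retained-correct RT at chunk positions is paired
#' against their mean at all other window positions.
#'
#' @param trials Annotated trial table (counting-task style).
#' @param chunk_stride Instructed chunk length, 3 or 5.
#' @param position_window Positions analysed (default 2..15; position 1 is
#'   always a program site and analysed separately).
#' @return A list of class `chunk_position_comparison`: `chunk_positions`,
#'   `other_positions`, `per_participant` (tibble of paired means) and
#'   `comparison` (a [paired_comparison()]).
#' @export
chunk_position_comparison <- function(trials, chunk_stride,
                                      position_window = 2:15) {
  if (length(chunk_stride) != 1L || !chunk_stride %in% c(3, 5)) {
    stop("`chunk_stride` must be 3 or 5", call. = FALSE)
  }
  chunk_pos <- position_window[(position_window - 1) %% chunk_stride == 0]
  other_pos <- setdiff(position_window, chunk_pos)
  if (length(chunk_pos) == 0L || length(other_pos) == 0L) {
    stop("position window yields an empty chunk or non-chunk set",
         call. = FALSE)
  }
  rows <- retained_rt(trials)
  rows <- rows[rows$position %in% position_window, , drop = FALSE]
  at_chunk <- rows$position %in% chunk_pos
  mean_by_part <- function(r) {
    tapply(r$rt_ms, r$participant, mean)
  }
  m_chunk <- mean_by_part(rows[at_chunk, , drop = FALSE])
  m_other <- mean_by_part(rows[!at_chunk, , drop = FALSE])
  parts <- intersect(names(m_chunk), names(m_other))
  per_part <- tibble::tibble(participant = parts,
                             chunk_mean = as.numeric(m_chunk[parts]),
                             other_mean = as.numeric(m_other[parts]))
  structure(list(
    chunk_positions = chunk_pos,
    other_positions = other_pos,
    per_participant = per_part,
    comparison = paired_comparison(per_part$chunk_mean, per_part$other_mean)
  ), class = "chunk_position_comparison")
}

#' @export
print.chunk_position_comparison <- function(x, ...) {
  cat("<chunk_position_comparison>\n")
  cat("  chunk positions:", x$chunk_positions, "\n")
  print(x$comparison)
  invisible(x)
}
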