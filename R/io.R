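#' Trial-table CSV schema
#'
#' Trial tables are written with a fixed, documented column order:
#' `participant, session, sequence_index, position, rule, is_switch,
#' is_congruent, is_chunk_start, rt_ms, correct, excluded, exclusion_reason`
#' (variant-specific metadata columns follow). Missing values — including
#' absent congruency — are encoded as empty fields.
#'
#' @return Character vector of the core column names, in order.
#' @export
trial_columns <- function() {
  c("participant", "session", "sequence_index", "position", "rule",
    "is_switch", "is_congruent", "is_chunk_start", "rt_ms", "correct",
    "excluded", "exclusion_reason")
}

#' Write / read trial tables
#'
#' @param trials A trial-record tibble.
#' @param path CSV file path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns a tibble with the schema's column types restored, and fails
#'   with an error naming the first missing required column.
#' @export
write_trials <- function(trials, path) {
  core <- intersect(trial_columns(), names(trials))
  extra <- setdiff(names(trials), core)
  utils::write.csv(trials[, c(core, extra)], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("participant", "session", "sequence_index", "position",
                "rule", "rt_ms", "correct")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("trial file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as_lgl <- function(x) ifelse(x == "", NA, x == "TRUE")
  df$sequence_index <- as.integer(df$sequence_index)
  df$position <- as.integer(df$position)
  df$rt_ms <- as.numeric(df$rt_ms)
  df$correct <- as_lgl(df$correct)
  for (col in c("is_switch", "is_congruent", "is_chunk_start", "excluded")) {
    if (col %in% names(df)) df[[col]] <- as_lgl(df[[col]])
  }
  if ("exclusion_reason" %in% names(df)) {
    df$exclusion_reason[df$exclusion_reason == ""] <- NA
  }
  if ("count_base" %in% names(df)) df$count_base <- as.integer(df$count_base)
  tibble::as_tibble(df)
}

#' Run configurations
#'
#' A `run_config` bundles everything a simulation run needs — variant,
#' parameter overrides, chunk-size distribution spec, run size, seed and
#' output directory — and serializes to a human-readable YAML file. A run's
#' config is echoed verbatim into its output directory, so archived runs can
#' be reproduced exactly.
#'
#' @param variant Experiment variant (see [experiment_design()]).
#' @param n_participants,n_sequences Optional design overrides.
#' @param params Named list of [rt_model_params()] overrides.
#' @param dist Chunk-size distribution spec (list form, see
#'   [chunk_dist_to_list()]) or `NULL` for the design default.
#' @param seed Integer seed.
#' @param count_base Counting base for `exp3`.
#' @param analysis_window Integer positions for the trend analyses (`NULL`
#'   lets [cmd_analyze()] default to 2..max).
#' @param out_dir Output directory.
#' @param file YAML path for `read_run_config()` / `write_run_config()`.
#' @param config A `run_config`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(variant = "exp1_switch", n_participants = NULL,
                       n_sequences = NULL, params = list(), dist = NULL,
                       seed = 1, count_base = 3, analysis_window = NULL,
                       out_dir = ".") {
  structure(list(variant = variant, n_participants = n_participants,
                 n_sequences = n_sequences, params = params,
                 dist = if (inherits(dist, "chunk_dist"))
                   chunk_dist_to_list(dist) else dist,
                 seed = as.integer(seed), count_base = count_base,
                 analysis_window = analysis_window, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @export
write_run_config <- function(config, file) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname run_config
#' @export
read_run_config <- function(file) {
  x <- yaml::read_yaml(file)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

#' Simulate a run to disk
#'
#' Runs [simulate_experiment()] under `config` and writes `trials.csv` (the
#' trial table, latent `is_chunk_start` truth included), `truth.json` (the
#' resolved generative parameters and chunk-size distribution — the sidecar
#' that lets analyses be scored against the simulation truth), `config.yaml`
#' (the config echoed verbatim) and `run.log` (a one-line provenance
#' record). Deterministic for a given seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (defaults to `config$out_dir`).
#' @return Invisibly, a named list of the written paths.
#' @export
cmd_simulate <- function(config, out_dir = config$out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- do.call(rt_model_params, config$params)
  trials <- simulate_experiment(
    config$variant,
    n_participants = config$n_participants,
    n_sequences = config$n_sequences,
    params = params,
    dist = config$dist,
    seed = config$seed,
    count_base = config$count_base %||% 3
  )
  paths <- list(
    trials = file.path(out_dir, "trials.csv"),
    truth = file.path(out_dir, "truth.json"),
    config = file.path(out_dir, "config.yaml"),
    log = file.path(out_dir, "run.log")
  )
  write_trials(trials, paths$trials)
  design <- experiment_design(config$variant,
                              n_participants = config$n_participants,
                              n_sequences = config$n_sequences,
                              count_base = config$count_base %||% 3,
                              dist = config$dist)
  jsonlite::write_json(
    list(params = unclass(params),
         dist = if (is.null(design$dist)) NULL else
           chunk_dist_to_list(design$dist),
         seed = config$seed, variant = config$variant,
         n_participants = design$n_participants,
         n_sequences = design$n_sequences),
    paths$truth, auto_unbox = TRUE, digits = NA, null = "null")
  write_run_config(config, paths$config)
  log_line(paths$log, sprintf("simulate variant=%s seed=%d rows=%d",
                              config$variant, config$seed, nrow(trials)))
  invisible(paths)
}

log_line <- function(path, msg) {
  cat(sprintf("[%s] %s | %s | chunksim %s\n",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg,
              R.version.string,
              as.character(utils::packageVersion("chunksim"))),
      file = path, append = TRUE)
}

#' Analyze a trial CSV to disk
#'
#' Reads a trial table, applies the exclusion chain, and writes
#' `exclusions.json` (the [apply_exclusions()] report), `profile.csv` (the
#' per-position profile) and `results.json` (RM-ANOVA and linear contrast
#' over the analysis window, plus switch/Stroop cost trajectories when the
#' table carries the relevant condition labels).
#'
#' @param trials_path Path to a schema-valid trial CSV.
#' @param out_dir Output directory.
#' @param analysis_window Integer positions for the trend tests (default
#'   2..max observed).
#' @return Invisibly, a list with the computed objects and written paths.
#' @export
cmd_analyze <- function(trials_path, out_dir = dirname(trials_path),
                        analysis_window = NULL) {
  trials <- read_trials(trials_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  excl <- apply_exclusions(trials)
  trials <- excl$trials

  if (is.null(analysis_window)) {
    analysis_window <- 2:max(trials$position)
  }
  prof <- position_profile(trials)
  m <- position_means_matrix(trials, positions = analysis_window)
  results <- list(
    analysis_window = analysis_window,
    rt_anova = unclass(rm_anova_oneway(m)),
    rt_linear_contrast = unclass(linear_contrast(m))
  )
  if (any(trials[["is_switch"]] %in% TRUE) &&
      any(trials[["is_switch"]] %in% FALSE)) {
    cp <- cost_profile(trials, "switch", positions = analysis_window)
    results$switch_cost_contrast <- unclass(cp$contrast)
  }
  if (any(trials[["is_congruent"]] %in% FALSE) &&
      any(trials[["is_congruent"]] %in% TRUE)) {
    cp <- cost_profile(trials, "stroop", positions = analysis_window)
    results$stroop_cost_contrast <- unclass(cp$contrast)
  }

  paths <- list(
    exclusions = file.path(out_dir, "exclusions.json"),
    profile = file.path(out_dir, "profile.csv"),
    results = file.path(out_dir, "results.json"),
    log = file.path(out_dir, "run.log")
  )
  write_exclusion_report(excl$report, paths$exclusions)
  utils::write.csv(prof, paths$profile, row.names = FALSE, na = "")
  jsonlite::write_json(results, paths$results, auto_unbox = TRUE,
                       digits = NA)
  log_line(paths$log, sprintf("analyze input=%s rows=%d",
                              basename(trials_path), nrow(trials)))
  invisible(list(trials = trials, report = excl$report, profile = prof,
                 results = results, paths = paths))
}

#' Run a chunking-scenario illustration to disk
#'
#' Runs [simulate_figure2()] for a named scenario and writes `profile.csv`
#' (per-position across-participant means with 95% CIs) and, optionally, a
#' PDF plot of the profile.
#'
#' @param scenario One of [chunking_presets()].
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param n_participants,n_sequences Run size.
#' @param plot Write `profile.pdf` (requires ggplot2).
#' @return Invisibly, a list with the profile and written paths.
#' @export
cmd_figure2 <- function(scenario = "u2_9", seed = 1, out_dir = ".",
                        n_participants = 16, n_sequences = 400,
                        plot = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- simulate_figure2(scenario, n_participants = n_participants,
                           n_sequences = n_sequences, seed = seed)
  paths <- list(profile = file.path(out_dir,
                                    paste0("profile_", scenario, ".csv")),
                log = file.path(out_dir, "run.log"))
  utils::write.csv(prof, paths$profile, row.names = FALSE)
  if (plot) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      stop("plotting requires the ggplot2 package", call. = FALSE)
    }
    paths$plot <- file.path(out_dir, paste0("profile_", scenario, ".pdf"))
    ggplot2::ggsave(paths$plot, plot_position_profile(prof),
                    width = 6, height = 4)
  }
  log_line(paths$log, sprintf("figure2 scenario=%s seed=%d", scenario, seed))
  invisible(list(profile = prof, paths = paths))
}

#' Plot a per-position profile
#'
#' Line plot of per-position means with 95% confidence-interval error bars,
#' in the style of the standard position-profile panels.
#'
#' @param profile A profile tibble with `position`, `mean_rt`, `ci_rt` (as
#'   returned by [simulate_figure2()] or [position_profile()]).
#' @return A ggplot object.
#' @export
plot_position_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$position, y = .data$mean_rt)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rt - .data$ci_rt,
                                        ymax = .data$mean_rt + .data$ci_rt),
                           width = 0.2) +
    ggplot2::scale_x_continuous(breaks = unique(profile$position)) +
    ggplot2::labs(x = "Trial position", y = "Mean RT (ms)") +
    ggplot2::theme_classic()
}
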