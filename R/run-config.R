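# Run configuration and the single-process end-to-end entry point used by
# the command-line wrapper (inst/cli/stepcoach.R).

#' Build or read a run configuration
#'
#' A run configuration bundles the goal profile, cohort spec (used when no
#' input CSV is given), forecaster settings, interval coverage, seed and
#' output directory. In a YAML file the sections are `goals`, `cohort`,
#' `forecaster`, and top-level `input`, `output_dir`, `coverage`, `seed`,
#' `forecaster_method`. Unknown keys and unresolvable paths fail validation
#' before anything is written; a missing mandatory goal key is named in the
#' error.
#'
#' @param path optional YAML file.
#' @param input optional daily CSV path (otherwise a cohort is synthesised).
#' @param output_dir directory for run artifacts.
#' @param goals a [goal_profile()].
#' @param cohort a [cohort_spec()].
#' @param fc_config a [forecaster_config()].
#' @param forecaster_method `"cnn"` or `"naive"`.
#' @param coverage interval coverage.
#' @param seed integer seed.
#' @return a `run_config` list.
#' @export
run_config <- function(path = NULL, input = NULL, output_dir = "stepcoach-run",
                       goals = goal_profile(), cohort = cohort_spec(),
                       fc_config = forecaster_config(),
                       forecaster_method = "cnn", coverage = 0.80,
                       seed = 1) {
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    known <- c("goals", "cohort", "forecaster", "input", "output_dir",
               "coverage", "seed", "forecaster_method")
    bad <- setdiff(names(y), known)
    if (length(bad)) {
      stop("unknown run config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (!is.null(y$goals)) goals <- do.call(goal_profile, y$goals)
    if (!is.null(y$cohort)) cohort <- do.call(cohort_spec, y$cohort)
    if (!is.null(y$forecaster)) {
      fc_config <- do.call(forecaster_config, y$forecaster)
    }
    if (!is.null(y$input)) input <- y$input
    if (!is.null(y$output_dir)) output_dir <- y$output_dir
    if (!is.null(y$coverage)) coverage <- y$coverage
    if (!is.null(y$seed)) seed <- y$seed
    if (!is.null(y$forecaster_method)) forecaster_method <- y$forecaster_method
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("input path not resolvable: ", input, call. = FALSE)
  }
  coverage_constant(coverage)  # validates the level
  structure(list(input = input, output_dir = output_dir, goals = goals,
                 cohort = cohort, fc_config = fc_config,
                 forecaster_method = forecaster_method,
                 coverage = coverage, seed = as.integer(seed)),
            class = "run_config")
}

#' Execute an end-to-end run
#'
#' Synthesises (or loads) the cohort, runs [run_pipeline()], and writes all
#' artifacts into the output directory: the daily cohort CSV, weekly summary
#' CSV, interval table CSV, daily and weekly recommendation JSON-lines logs,
#' the knowledge-base Turtle export, and a `run-info.json` stamped with the
#' seed and a hash of the configuration.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the pipeline result and the artifact
#'   paths.
#' @export
run <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  daily <- if (!is.null(config$input)) {
    read_daily_csv(config$input)
  } else {
    synthesize_daily_cohort(config$cohort)
  }
  res <- run_pipeline(daily, goals = config$goals,
                      forecaster = config$forecaster_method,
                      fc_config = config$fc_config,
                      coverage = config$coverage, seed = config$seed)
  paths <- file.path(config$output_dir,
                     c(daily = "daily.csv", weekly = "weekly_summary.csv",
                       intervals = "intervals.csv",
                       daily_log = "daily_recommendations.jsonl",
                       weekly_log = "weekly_recommendations.jsonl",
                       kb = "knowledge_base.ttl", info = "run-info.json"))
  names(paths) <- c("daily", "weekly", "intervals", "daily_log",
                    "weekly_log", "kb", "info")
  write_daily_csv(daily, paths["daily"])
  all_sum <- unlist(res$weekly_summaries, recursive = FALSE)
  if (length(all_sum)) {
    write.csv(weekly_summary_table(all_sum), paths["weekly"],
              row.names = FALSE)
  }
  if (!is.null(res$intervals)) {
    write.csv(res$intervals, paths["intervals"], row.names = FALSE)
  }
  if (!is.null(res$daily_log)) {
    write_recommendation_log(res$daily_log, paths["daily_log"])
  }
  if (!is.null(res$weekly_log)) {
    write_recommendation_log(res$weekly_log, paths["weekly_log"])
  }
  export_rdf(res$kb, paths["kb"])
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config[c("forecaster_method", "coverage", "seed")],
                       cfg_file, auto_unbox = TRUE)
  jsonlite::write_json(
    list(seed = config$seed,
         config_hash = unname(tools::md5sum(cfg_file)),
         n_participants = length(unique(daily$participant)),
         n_days = nrow(daily),
         skipped = as.list(res$skipped)),
    paths["info"], auto_unbox = TRUE)
  invisible(list(result = res, paths = paths))
}
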