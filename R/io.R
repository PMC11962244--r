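# CSV readers/writers for the three dataset kinds, JSON truth sidecars,
# and the end-to-end pipeline: simulate/read -> model selection -> metrics
# -> bootstrap trends -> quantile and cohort analyses -> report bundle.
# Readers validate strictly and never silently coerce invalid rows.

read_csv_checked <- function(path, required) {
  stop_if(!file.exists(path), "file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  stop_if(length(missing) > 0,
          "missing column(s) in ", basename(path), ": ",
          paste(missing, collapse = ", "))
  df
}

bad_rows <- function(idx) paste(idx, collapse = ", ")

#' Read transect survey records from CSV
#'
#' Expects columns `date` (ISO-8601), `count`, `route_length_km`.  Derives
#' `year` and 1-based `doy`.  Rows with unparseable dates, negative counts
#' or non-positive efforts abort the read with their row numbers; duplicate
#' dates are allowed but flagged in the `"duplicate_dates"` attribute.
#'
#' @param path CSV file path.
#' @return a `survey_data` data frame.
#' @export
read_survey_csv <- function(path) {
  df <- read_csv_checked(path, c("date", "count", "route_length_km"))
  if (nrow(df) == 0) {
    out <- data.frame(date = as.Date(character()), year = integer(),
                      doy = integer(), count = integer(),
                      route_length_km = numeric())
    return(structure(out, class = c("survey_data", "data.frame")))
  }
  d <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  stop_if(anyNA(d), "unparseable ISO-8601 date(s) in row(s): ",
          bad_rows(which(is.na(d))))
  cnt <- suppressWarnings(as.numeric(df$count))
  stop_if(anyNA(cnt) || any(cnt < 0),
          "invalid count(s) (missing or negative) in row(s): ",
          bad_rows(which(is.na(cnt) | cnt < 0)))
  eff <- suppressWarnings(as.numeric(df$route_length_km))
  stop_if(anyNA(eff) || any(eff <= 0),
          "invalid route length(s) (must be > 0) in row(s): ",
          bad_rows(which(is.na(eff) | eff <= 0)))
  out <- data.frame(date = d, year = as.integer(format(d, "%Y")),
                    doy = day_of_year(d), count = cnt,
                    route_length_km = eff)
  dup <- unique(as.character(d[duplicated(d)]))
  structure(out, duplicate_dates = dup,
            class = c("survey_data", "data.frame"))
}

#' Write transect survey records to CSV
#' @param x a `survey_data` frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_survey_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("date", "count", "route_length_km")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read specimen records from CSV
#'
#' Expects columns `year`, `doy` (1-366) and `region`.
#'
#' @param path CSV file path.
#' @return a `specimen_data` data frame.
#' @export
read_specimen_csv <- function(path) {
  df <- read_csv_checked(path, c("year", "doy", "region"))
  if (nrow(df)) {
    yr <- suppressWarnings(as.integer(df$year))
    doy <- suppressWarnings(as.integer(df$doy))
    stop_if(anyNA(yr), "invalid year(s) in row(s): ", bad_rows(which(is.na(yr))))
    stop_if(anyNA(doy) || any(doy < 1 | doy > 366),
            "day of year outside [1, 366] in row(s): ",
            bad_rows(which(is.na(doy) | doy < 1 | doy > 366)))
    df$year <- yr; df$doy <- doy
  }
  structure(df, class = c("specimen_data", "data.frame"))
}

#' Write specimen records to CSV
#' @param x a `specimen_data` frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_specimen_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("year", "doy", "region")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cohort-experiment records from CSV
#'
#' `path` holds the cage table (`site`, `cage`, `cohort`, `n_released`,
#' `n_eclosed`); `survivors_path` optionally holds one row per surviving
#' individual (`cage`, `site`, `cohort`, `dev_days`).
#'
#' @param path cage-level CSV.
#' @param survivors_path optional per-survivor CSV.
#' @return a `cohort_data` object.
#' @export
read_cohort_csv <- function(path, survivors_path = NULL) {
  cages <- read_csv_checked(path, c("site", "cage", "cohort",
                                    "n_released", "n_eclosed"))
  bad <- which(cages$n_eclosed > cages$n_released | cages$n_eclosed < 0 |
                 cages$n_released < 0)
  stop_if(length(bad) > 0,
          "need 0 <= n_eclosed <= n_released; offending row(s): ",
          bad_rows(bad))
  survivors <- if (!is.null(survivors_path))
    read_csv_checked(survivors_path, c("cage", "cohort", "dev_days"))
  else data.frame(cage = character(), site = integer(),
                  cohort = character(), dev_days = numeric())
  structure(list(cages = cages, survivors = survivors),
            class = "cohort_data")
}

#' Write cohort-experiment records to CSV
#' @param x a `cohort_data` object.
#' @param path cage-level CSV path.
#' @param survivors_path optional per-survivor CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path, survivors_path = NULL) {
  utils::write.csv(x$cages[, c("site", "cage", "cohort", "n_released",
                               "n_eclosed")],
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(survivors_path))
    utils::write.csv(x$survivors, survivors_path, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write the ground-truth sidecar of a simulated dataset
#'
#' @param x a simulated dataset (from one of the `simulate_*()`
#'   generators).
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(x, path) {
  truth <- sim_truth(x)
  stop_if(is.null(truth), "object carries no truth record")
  clean <- rapply(truth, unclass, how = "replace")
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Either file paths or simulation parameter objects may be given for each
#' dataset kind; `NULL` skips that analysis stage.
#'
#' @param surveys path to a survey CSV, a `survey_data` frame, or a
#'   [survey_sim_params()] object to simulate from.
#' @param specimens path, `specimen_data` frame, or
#'   [specimen_sim_params()].
#' @param cohorts path (cage CSV), `cohort_data`, or
#'   [experiment_sim_params()].
#' @param survivors_path optional per-survivor CSV when `cohorts` is a
#'   path.
#' @param specs list of [model_spec()] candidates for model selection.
#' @param prominence_frac peak prominence filter fraction.
#' @param n_reps,alpha bootstrap settings.
#' @param taus quantiles for the specimen trend report.
#' @param reference_effort effort (km) curves are standardized to.
#' @param seed master seed for simulation and the bootstrap.
#' @param out_dir output directory (created if missing); `NULL` disables
#'   file output.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(surveys = survey_sim_params(),
                            specimens = specimen_sim_params(),
                            cohorts = experiment_sim_params(),
                            survivors_path = NULL,
                            specs = list(model_spec("doy_only"),
                                         model_spec("additive"),
                                         model_spec("interaction")),
                            prominence_frac = 0.01,
                            n_reps = 500, alpha = 0.05,
                            taus = c(0.1, 0.5, 0.9),
                            reference_effort = 1,
                            seed = 1, out_dir = NULL) {
  stop_if(n_reps < 1, "n_reps must be >= 1")
  for (p in list(surveys, specimens, cohorts))
    if (is.character(p)) stop_if(!file.exists(p), "file not found: ", p)
  structure(list(surveys = surveys, specimens = specimens,
                 cohorts = cohorts, survivors_path = survivors_path,
                 specs = specs, prominence_frac = prominence_frac,
                 n_reps = n_reps, alpha = alpha, taus = taus,
                 reference_effort = reference_effort,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

resolve_dataset <- function(x, reader, simulator, seed) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) return(reader(x))
  if (inherits(x, c("survey_sim_params", "specimen_sim_params",
                    "experiment_sim_params"))) {
    if (is.null(x$seed)) x$seed <- seed
    return(simulator(x))
  }
  x
}

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain each dataset (read or simulate); (2) seasonal model
#' selection; (3) per-year phenometrics from the winning model; (4)
#' bootstrap trend assessment; (5) specimen quantile trends; (6) cohort
#' survival and development-time models.  Stage failures are recorded in
#' the manifest and later independent stages still run.  Given the same
#' config and seed the result is deterministic.
#'
#' @param config a [pipeline_config()].
#' @return a list (class `pipeline_result`) with elements `selection`,
#'   `metrics`, `trends`, `quantiles`, `survival`, `devtime`, and
#'   `manifest`; if `out_dir` is set, metric/trend CSVs, fit JSONs and the
#'   manifest are also written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("phenodem")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  res <- list()
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      structure(list(message = conditionMessage(e)), class = "stage_failure")
    })
    manifest$stages[[name]] <<-
      if (inherits(out, "stage_failure")) list(status = "failed",
                                               message = out$message)
      else list(status = "ok")
    out
  }

  surveys <- stage("surveys_data",
    resolve_dataset(config$surveys, read_survey_csv, simulate_surveys,
                    config$seed))
  specimens <- stage("specimens_data",
    resolve_dataset(config$specimens, read_specimen_csv, simulate_specimens,
                    config$seed + 1L))
  cohorts <- stage("cohorts_data", {
    if (is.character(config$cohorts))
      read_cohort_csv(config$cohorts, config$survivors_path)
    else resolve_dataset(config$cohorts, read_cohort_csv,
                         simulate_experiment, config$seed + 2L)
  })

  ok <- function(x) !is.null(x) && !inherits(x, "stage_failure")

  if (ok(surveys)) {
    res$selection <- stage("model_selection",
      model_selection_table(surveys, config$specs, alpha = config$alpha))
    if (ok(res$selection)) {
      win_fit <- res$selection$fits[[res$selection$winner]]
      res$metrics <- stage("phenometrics",
        annual_phenometrics(win_fit, prominence_frac = config$prominence_frac,
                            reference_effort = config$reference_effort))
      res$trends <- stage("bootstrap_trends",
        bootstrap_trends(surveys, win_fit$spec, n_reps = config$n_reps,
                         alpha = config$alpha, seed = config$seed,
                         prominence_frac = config$prominence_frac,
                         reference_effort = config$reference_effort))
    }
  }
  if (ok(specimens) && nrow(specimens) > 0)
    res$quantiles <- stage("quantile_trends",
      quantile_phenology_report(specimens, taus = config$taus))
  if (ok(cohorts)) {
    res$survival <- stage("survival_glmm", fit_survival_glmm(cohorts))
    res$devtime <- stage("devtime_lmm", fit_devtime_lmm(cohorts))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    if (ok(res$metrics))
      utils::write.csv(as.data.frame(res$metrics),
                       file.path(od, "phenometrics.csv"), row.names = FALSE)
    if (ok(res$trends)) {
      tr <- do.call(rbind, lapply(res$trends, function(b)
        data.frame(metric = b$metric, slope = b$original$slope,
                   p = b$original$p,
                   prop_sig_positive = b$prop_sig_positive,
                   prop_sig_negative = b$prop_sig_negative)))
      utils::write.csv(tr, file.path(od, "trend_summary.csv"),
                       row.names = FALSE)
    }
    if (ok(res$quantiles))
      utils::write.csv(res$quantiles$table,
                       file.path(od, "quantile_trends.csv"),
                       row.names = FALSE)
    if (ok(res$selection))
      write_model_json(res$selection$fits[[res$selection$winner]],
                       file.path(od, "winning_model.json"))
    manifest$config <- list(
      n_reps = config$n_reps, alpha = config$alpha, taus = config$taus,
      prominence_frac = config$prominence_frac,
      reference_effort = config$reference_effort)
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  res$manifest <- manifest
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run (seed", x$manifest$seed, ")\n")
  for (nm in names(x$manifest$stages))
    cat(sprintf("  %-18s %s\n", nm, x$manifest$stages[[nm]]$status))
  invisible(x)
}
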