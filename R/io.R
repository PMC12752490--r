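REQUIRED_TRIAL_COLS <- c("animal_id", "day", "time_min", "vo2_l_min")

# tiny 32-bit polynomial hash for config provenance headers (hex string);
# arithmetic stays below 2^53 so the result is exact in doubles
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_with_header <- function(df, path, seed = NULL, hash = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# generated_by=hifresp %s",
                     as.character(utils::packageVersion("hifresp"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", seed), con)
  if (!is.null(hash)) writeLines(sprintf("# config_hash=%s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Read a trial table
#'
#' Reads a comma-separated trial table (UTF-8, header row, `#` comment lines
#' allowed). Column names carry their units (`time_min`, `vo2_l_min`,
#' `mass_kg`, ...), and the reader errors on any missing required column;
#' unknown extra columns are accepted with a message.
#'
#' @param path file path.
#' @return Data frame of typed trial rows.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("trial table is empty: ", path)
  miss <- setdiff(REQUIRED_TRIAL_COLS, names(df))
  if (length(miss))
    stop("trial table is missing required column(s): ",
         paste(miss, collapse = ", "))
  known <- c(REQUIRED_TRIAL_COLS, "vco2_l_min", "rer", "intake_kcal",
             "meal_fraction", "age_yr", "mass_kg", "pool_temp_c", "sex",
             "true_vo2_l_min", "breath_rate_min", "vt_mean_l")
  extra <- setdiff(names(df), known)
  if (length(extra))
    message("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  if (!is.numeric(df$time_min) || !is.numeric(df$vo2_l_min))
    stop("time_min and vo2_l_min must be numeric ",
         "(check the unit-suffixed column names)")
  df
}

#' Write a trial table
#'
#' @param trials data frame of trial rows.
#' @param path output file path.
#' @param seed,config optional provenance recorded in the `#` header.
#' @export
write_trial_table <- function(trials, path, seed = NULL, config = NULL) {
  write_with_header(trials, path, seed = seed,
                    hash = if (is.null(config)) NULL else config_hash(config))
  invisible(path)
}

#' Read an animal metadata table
#'
#' @param path file path to a CSV with at least `animal_id`, `mass_kg` and
#'   `maturity` columns.
#' @return Data frame.
#' @export
read_animal_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("animal_id", "mass_kg", "maturity"), names(df))
  if (length(miss))
    stop("animal table is missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Write or read a signal trace
#'
#' Traces are stored as delimited text: a `#`-prefixed `key=value` header
#' block (sample_rate, units, channel metadata) followed by a CSV body with a
#' time column in seconds and one column per channel.
#'
#' @param trace a [flow_trace()] or [gas_trace()].
#' @param path file path.
#' @return `write_trace` returns the path invisibly; `read_trace` the
#'   reconstructed trace object.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate=%.10g", trace$sample_rate), con)
  writeLines("# time_units=s", con)
  if (inherits(trace, "flow_trace")) {
    writeLines(c("# channel=flow", "# flow_units=l_per_s",
                 "# sign_convention=expiration_positive"), con)
    utils::write.csv(data.frame(time = trace$time, flow = trace$flow), con,
                     row.names = FALSE)
  } else if (inherits(trace, "gas_trace")) {
    writeLines(c("# channel=gas",
                 sprintf("# t90_o2=%.10g", trace$t90_o2),
                 sprintf("# t90_co2=%.10g", trace$t90_co2),
                 sprintf("# transport_delay=%.10g", trace$transport_delay)),
               con)
    utils::write.csv(data.frame(time = trace$time, fo2 = trace$fo2,
                                fco2 = trace$fco2), con, row.names = FALSE)
  } else stop("unsupported trace type")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  df <- utils::read.csv(path, comment.char = "#")
  fs <- as.numeric(meta[["sample_rate"]])
  if (identical(meta[["channel"]], "flow")) {
    flow_trace(df$time, df$flow, fs)
  } else if (identical(meta[["channel"]], "gas")) {
    gas_trace(df$time, df$fo2, df$fco2, fs,
              t90_o2 = as.numeric(meta[["t90_o2"]]),
              t90_co2 = as.numeric(meta[["t90_co2"]]),
              transport_delay = as.numeric(meta[["transport_delay"]]))
  } else stop("unknown channel in trace header: ", path)
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; instrument keys live under an
#' `instrument:` block mirroring [instrument_model()]. Missing keys take the
#' package defaults.
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  inst <- do.call(instrument_model, y$instrument %||% list())
  y$instrument <- NULL
  do.call(sim_config, c(y, list(instrument = inst)))
}

#' Packaged fasted-energetics summary table
#'
#' Per-animal fasted summary of the emulated eight-dolphin study (basal
#' metabolic rate with trial counts, Kleiber ratio, maximal postprandial rise,
#' SDA scope, postabsorptive respiratory exchange ratio), as printed in the
#' source study's summary tables.
#'
#' @return Data frame with one row per animal.
#' @export
dolphin_fasted_summary <- function() {
  utils::read.csv(system.file("extdata", "fasted_summary.csv",
                              package = "hifresp"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Packaged animal metadata table
#'
#' Identity, sex, age, body mass, meal energy and meal fraction for the eight
#' study animals (second intake level, where tested, in the `intake_kcal_2` /
#' `pct_daily_2` columns).
#'
#' @return Data frame with one row per animal.
#' @export
dolphin_animals <- function() {
  utils::read.csv(system.file("extdata", "animal_summary.csv",
                              package = "hifresp"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Packaged study-level printed means
#'
#' Study-level marginal means used as worked-example inputs: mean energy
#' intake and meal fraction, mean body mass, the model-predicted total O2
#' volume over the 133-min window, and the study-mean BMR.
#'
#' @return A named list.
#' @export
study_means <- function() {
  df <- utils::read.csv(system.file("extdata", "study_means.csv",
                                    package = "hifresp"),
                        comment.char = "#", stringsAsFactors = FALSE)
  as.list(stats::setNames(df$value, df$quantity))
}

#' Run the full synthetic-study pipeline
#'
#' Executes the four stages in order: (1) simulate a study trial table and one
#' raw demo recording; (2) process the raw recording into a trial measurement;
#' (3) fit the time-course model and integrate the population curve; (4)
#' derive the energetics report and HIF summary. All artefacts are written to
#' `outdir` as delimited text with seed/config-hash headers; stage progress is
#' logged to stderr and to `run.log` in `outdir`. A stage failure aborts with
#' the stage name in the error message.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing).
#' @param seed integer seed for model resampling and the demo recording.
#' @param n_samples posterior draws for the AUC interval.
#' @param window AUC window in minutes.
#' @param verbose logical; log stage progress to stderr.
#' @return A list with `trials`, `demo_trial`, `fit`, `curve`, `auc`,
#'   `report`, `hif` (invisible).
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempdir(),
                         seed = 1L, n_samples = 1000,
                         window = c(0, 133), verbose = TRUE) {
  if (config$n_animals < 1) stop("config must include at least one animal")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  # stage log goes to stderr and to a run-log file; results never live only
  # in the log
  log_file <- file.path(outdir, "run.log")
  cat(sprintf("hifresp %s run, seed=%d\n",
              as.character(utils::packageVersion("hifresp")), seed),
      file = log_file)
  log_msg <- function(...) {
    line <- sprintf(...)
    if (verbose) message(line)
    cat(line, "\n", file = log_file, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  hash <- config_hash(config)

  log_msg("[simulate] %d animals x %d trials x %d timepoints",
          config$n_animals, config$trials_per_animal,
          length(config$timepoints))
  ds <- stage("simulate", make_study_dataset(config))
  write_trial_table(ds$trials, file.path(outdir, "trials.csv"),
                    seed = config$seed, config = config)
  write_with_header(ds$animals, file.path(outdir, "animals.csv"),
                    seed = config$seed, hash = hash)

  log_msg("[process] demo raw recording (%d Hz)",
          config$instrument$sample_rate)
  rec <- stage("process",
               simulate_trial_recording(config$baseline_vo2, config$rer_mean,
                                        duration = 6, config = config,
                                        seed = seed))
  demo <- stage("process",
                process_trial(rec$flow, rec$gas, duration = 6,
                              animal_id = "demo", time_since_feeding = 0))
  write_with_header(
    data.frame(animal_id = "demo", time_min = 0,
               vo2_l_min = demo$vo2_rate, vco2_l_min = demo$vco2_rate,
               rer = demo$rer, breath_rate_min = demo$breath_rate,
               vt_mean_l = demo$vt_mean),
    file.path(outdir, "demo_trial.csv"), seed = seed, hash = hash)

  log_msg("[fit] %d rows", nrow(ds$trials))
  fit <- stage("fit", fit_timecourse(ds$trials))
  curve <- stage("fit", suppressWarnings(
    population_curve(fit, grid = seq(window[1], window[2], by = 1),
                     n_samples = n_samples, seed = seed)))
  auc <- stage("fit", auc_timecourse(curve, window = window))
  write_with_header(as.data.frame(curve[, c("time", "vo2", "lower",
                                            "upper")]),
                    file.path(outdir, "population_curve.csv"),
                    seed = seed, hash = hash)

  log_msg("[energetics] %d animals", nrow(ds$animals))
  report <- stage("energetics", summarize_individuals(ds$trials, ds$animals))
  bmr <- report$study$bmr_mean
  hif <- stage("energetics",
               hif_summary(auc$point, bmr, window = diff(window),
                           gei = mean(ds$animals$intake_kcal),
                           meal_fraction = mean(ds$animals$meal_fraction),
                           rmr_tail = NULL))
  write_with_header(report$per_animal, file.path(outdir, "per_animal.csv"),
                    seed = seed, hash = hash)
  write_with_header(
    data.frame(quantity = c("auc_l", "auc_se_l", "baseline_l", "excess_l",
                            "hif_pct_gei", "daily_digestive_l",
                            "daily_pct_bmr", "study_bmr_l_min"),
               value = c(auc$point, auc$se, hif$baseline_volume,
                         hif$excess_volume, hif$hif_pct_gei,
                         hif$daily_digestive_volume, hif$daily_pct_bmr,
                         bmr)),
    file.path(outdir, "hif_summary.csv"), seed = seed, hash = hash)
  log_msg("[done] outputs in %s", outdir)
  invisible(list(trials = ds$trials, demo_trial = demo, fit = fit,
                 curve = curve, auc = auc, report = report, hif = hif))
}
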