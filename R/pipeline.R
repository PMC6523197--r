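# Orchestration: one reproducible run from simulated cohort to the five
# report artifacts (feature table, condition comparison, subset-search
# report, confusion matrices, per-trial temporal accuracy).

#' Configuration for a full experiment run
#'
#' @param n_subjects,n_trials Cohort dimensions.
#' @param seed Master seed; every random stage derives its seed from it.
#' @param profiles Named list of four `condition_profile`s.
#' @param bands A [spectral_bands()].
#' @param fatigue Per-trial separation multipliers (see
#'   [generate_cohort()]); the default attenuates conditions toward
#'   baseline at trials 10-11 with partial recovery at trial 12, emulating
#'   reduced autonomic separation late in a 24-h wakefulness protocol.
#' @param classifiers Character vector of classifier families to evaluate.
#' @param search If `TRUE`, run the exhaustive subset search per
#'   classifier; otherwise evaluate the full 8-feature set only.
#' @param temporal_classifiers Families (among `classifiers`) whose best
#'   models are carried into the temporal-generalization analysis.
#' @param ecg_window_s,eda_window_s Extraction windows, s.
#' @param out_dir Output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_subjects = 16, n_trials = 12, seed = 1,
                       profiles = default_condition_profiles(),
                       bands = spectral_bands(),
                       fatigue = c(rep(1, 9), 0.45, 0.45, 0.75),
                       classifiers = names(classifier_roster()),
                       search = TRUE,
                       temporal_classifiers = c("KNN", "LSVM"),
                       ecg_window_s = 240, eda_window_s = 120,
                       out_dir = tempfile("ansid_run_")) {
  stopifnot(n_subjects >= 2, n_trials >= 1)
  if (!all(temporal_classifiers %in% classifiers))
    stop("run_config: temporal_classifiers must be among classifiers")
  structure(list(n_subjects = n_subjects, n_trials = n_trials, seed = seed,
                 profiles = profiles, bands = bands,
                 fatigue = rep_len(fatigue, n_trials),
                 classifiers = classifiers, search = search,
                 temporal_classifiers = temporal_classifiers,
                 ecg_window_s = ecg_window_s, eda_window_s = eda_window_s,
                 out_dir = out_dir),
            class = "run_config")
}

config_json <- function(config) {
  ser <- list(
    n_subjects = config$n_subjects, n_trials = config$n_trials,
    seed = config$seed,
    profiles = lapply(config$profiles, unclass),
    bands = unclass(config$bands),
    fatigue = config$fatigue, classifiers = config$classifiers,
    search = config$search,
    temporal_classifiers = config$temporal_classifiers,
    ecg_window_s = config$ecg_window_s,
    eda_window_s = config$eda_window_s)
  jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Extract the feature table directly from cohort parameters
#'
#' Streams the cohort: each recording is simulated, its eight indices
#' extracted, and the signals discarded, keeping memory flat. Equivalent to
#' `assemble_features(generate_cohort(...))`.
#'
#' @inheritParams generate_cohort
#' @param bands A [spectral_bands()].
#' @param ecg_window_s,eda_window_s Extraction windows, s.
#' @param verbose Progress messages per subject.
#' @return Labelled feature table as from [assemble_features()].
#' @export
cohort_features <- function(n_subjects = 16, n_trials = 12,
                            profiles = default_condition_profiles(),
                            seed = 1, fatigue = NULL,
                            subject_sd = list(),
                            bands = spectral_bands(),
                            ecg_window_s = 240, eda_window_s = 120,
                            verbose = FALSE) {
  if (is.null(fatigue)) fatigue <- rep(1, n_trials)
  fatigue <- rep_len(fatigue, n_trials)
  ids <- vapply(profiles, `[[`, "", "condition_label")
  names(profiles) <- ids
  eff <- do.call(draw_subject_effects,
                 c(list(n_subjects = n_subjects, seed = seed), subject_sd))
  rows <- list(); dropped <- character(0)
  for (s in seq_len(n_subjects)) {
    if (verbose) message("subject ", s, "/", n_subjects)
    for (tr in seq_len(n_trials))
      for (ci in seq_along(condition_levels())) {
        cond <- condition_levels()[ci]
        rec <- simulate_recording(profiles[[cond]], profiles[["BL"]],
                                  eff[[s]], s, tr, ci, seed,
                                  lambda = fatigue[tr],
                                  ecg_duration = ecg_window_s + 4,
                                  eda_duration = eda_window_s + 4)
        row <- tryCatch(
          extract_recording_features(rec, bands = bands,
                                     ecg_window_s = ecg_window_s,
                                     eda_window_s = eda_window_s),
          error = function(e) e)
        if (inherits(row, "error"))
          dropped <- c(dropped, sprintf("s%d t%d %s: %s", s, tr, cond,
                                        conditionMessage(row)))
        else rows[[length(rows) + 1L]] <- row
      }
  }
  if (!length(rows)) stop("cohort_features: no recording could be processed")
  out <- do.call(rbind, rows)
  attr(out, "dropped") <- dropped
  out
}

#' Run the full experiment
#'
#' Simulates the configured cohort, extracts the eight indices per
#' recording, and performs the three analyses: the repeated-measurements
#' condition comparison (trial 1), the classification study with optional
#' exhaustive subset search (trial 1, leave-one-subject-out), and the
#' temporal-generalization evaluation (train on trial 1, test on each later
#' trial). Writes five artifacts plus config and log to `out_dir`:
#' `features.csv`, `comparison.csv` (+ `comparison.txt`),
#' `subset_search.csv`, `confusion_matrices.csv`,
#' `temporal_accuracy.csv`, `config.json`, `run_log.json`.
#'
#' @param config A [run_config()].
#' @param verbose Progress messages.
#' @return Invisibly, a list with `features`, `comparison`, `search`
#'   (per-classifier), `best_table`, `confusions`, `temporal`, `config`,
#'   `timings`.
#' @export
run_experiment <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  say <- function(...) if (verbose) message(...)

  say("[1/4] simulating cohort and extracting features")
  tic <- Sys.time()
  features <- cohort_features(
    n_subjects = config$n_subjects, n_trials = config$n_trials,
    profiles = config$profiles, seed = config$seed,
    fatigue = config$fatigue, bands = config$bands,
    ecg_window_s = config$ecg_window_s,
    eda_window_s = config$eda_window_s, verbose = verbose)
  timings$extract_s <- as.numeric(Sys.time() - tic, units = "secs")
  utils::write.csv(features, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)

  trial1 <- features[features$trial == 1, , drop = FALSE]

  say("[2/4] repeated-measurements comparison")
  tic <- Sys.time()
  comparison <- comparison_report(trial1)
  timings$comparison_s <- as.numeric(Sys.time() - tic, units = "secs")
  utils::write.csv(comparison$table,
                   file.path(config$out_dir, "comparison.csv"),
                   row.names = FALSE)
  writeLines(format_comparison_report(comparison),
             file.path(config$out_dir, "comparison.txt"))

  say("[3/4] classification (LOSO", if (config$search)
    " + exhaustive subset search", ")")
  tic <- Sys.time()
  searches <- list()
  best_rows <- list()
  for (fam in config$classifiers) {
    spec <- classifier_spec(fam)
    if (config$search) {
      sr <- subset_search(trial1, spec)
      searches[[fam]] <- sr
      best_rows[[fam]] <- data.frame(
        model = fam, accuracy = sr$best$accuracy,
        indices = paste(sr$best$subset, collapse = ", "))
    } else {
      cv <- loso_cv(trial1, spec)
      searches[[fam]] <- list(best = cv)
      best_rows[[fam]] <- data.frame(
        model = fam, accuracy = cv$accuracy,
        indices = paste(feature_names(), collapse = ", "))
    }
    say("  ", fam, ": ",
        sprintf("%.1f%%", 100 * best_rows[[fam]]$accuracy))
  }
  best_table <- do.call(rbind, c(best_rows, make.row.names = FALSE))
  best_table <- best_table[order(-best_table$accuracy), ]
  timings$classification_s <- as.numeric(Sys.time() - tic, units = "secs")
  utils::write.csv(best_table,
                   file.path(config$out_dir, "subset_search.csv"),
                   row.names = FALSE)

  # confusion matrices for the two best models
  top2 <- utils::head(best_table$model, 2)
  conf_rows <- list()
  confusions <- list()
  for (fam in top2) {
    cm <- searches[[fam]]$best$confusion
    confusions[[fam]] <- cm
    df <- as.data.frame(cm)
    df$model <- fam
    conf_rows[[fam]] <- df
  }
  utils::write.csv(do.call(rbind, c(conf_rows, make.row.names = FALSE)),
                   file.path(config$out_dir, "confusion_matrices.csv"),
                   row.names = FALSE)

  say("[4/4] temporal generalization")
  tic <- Sys.time()
  temporal <- NULL
  if (config$n_trials >= 2) {
    temp_rows <- list()
    for (fam in config$temporal_classifiers) {
      sub <- searches[[fam]]$best$subset
      tg <- temporal_generalization(features, classifier_spec(fam), sub)
      tg$model <- fam
      temp_rows[[fam]] <- tg
    }
    temporal <- do.call(rbind, c(temp_rows, make.row.names = FALSE))
  } else {
    temporal <- data.frame(trial = integer(0), accuracy = numeric(0),
                           n = integer(0), model = character(0))
  }
  timings$temporal_s <- as.numeric(Sys.time() - tic, units = "secs")
  utils::write.csv(temporal,
                   file.path(config$out_dir, "temporal_accuracy.csv"),
                   row.names = FALSE)

  timings$total_s <- as.numeric(Sys.time() - t0, units = "secs")
  writeLines(config_json(config), file.path(config$out_dir, "config.json"))
  jsonlite::write_json(
    list(seed = config$seed, timings = timings,
         r_version = R.version.string,
         package_version = as.character(utils::packageVersion("ansid")),
         n_feature_rows = nrow(features),
         dropped = attr(features, "dropped"),
         finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(config$out_dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(features = features, comparison = comparison,
                 search = searches, best_table = best_table,
                 confusions = confusions, temporal = temporal,
                 config = config, timings = timings))
}
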