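# File interchange: timestamped CSV for EEG and kinematics (first column
# `time` in seconds, then one column per channel/coordinate), JSON for
# fitted models and run configuration, YAML or JSON for config files.

read_timestamped_csv <- function(path, what) {
  if (!file.exists(path)) abort(paste0(what, " file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time" %in% names(df)) {
    abort(paste0(what, " file must have a `time` column: ", path))
  }
  raw_names <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                     name_repair = "minimal"))
  if (anyDuplicated(raw_names)) {
    abort(paste0("duplicate column label in ", path, ": ",
                 paste(unique(raw_names[duplicated(raw_names)]), collapse = ", ")))
  }
  signal_rate(df) # validates monotone, regular timestamps
  df
}

#' Read / write EEG and kinematics CSV files
#'
#' The dialect is a header row (`time`, then channel or coordinate
#' labels) and one row per sample; the sampling rate is inferred from the
#' median timestamp increment and more than 1% jitter is rejected.
#'
#' @param path CSV file path.
#' @return A tibble with `time` plus channel/coordinate columns.
#' @export
read_eeg_csv <- function(path) {
  df <- read_timestamped_csv(path, "EEG")
  if (length(channel_names(df)) < 1) abort("EEG file has no channel columns")
  df
}

#' @rdname read_eeg_csv
#' @export
read_kin_csv <- function(path) {
  df <- read_timestamped_csv(path, "kinematics")
  d <- length(channel_names(df))
  if (!d %in% 2:3) {
    abort(sprintf("kinematics file must have 2 or 3 coordinate columns, found %d", d))
  }
  df
}

#' @rdname read_eeg_csv
#' @param df Tibble to write.
#' @export
write_timeseries_csv <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write a trial set to paired CSV files plus a JSON manifest
#'
#' Each trial k becomes `trial<k>_eeg.csv`, `trial<k>_kin.csv`, and
#' `trial<k>_eog.csv`; `manifest.json` records the forward-model
#' configuration and the true encoding weights.
#'
#' @param trials A `trial_set`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_trial_set <- function(trials, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in seq_along(trials)) {
    write_timeseries_csv(trials[[k]]$eeg, file.path(dir, sprintf("trial%d_eeg.csv", k)))
    write_timeseries_csv(trials[[k]]$kin, file.path(dir, sprintf("trial%d_kin.csv", k)))
    write_timeseries_csv(trials[[k]]$eog, file.path(dir, sprintf("trial%d_eog.csv", k)))
  }
  cfg <- attr(trials, "config")
  manifest <- list(
    n_trials = length(trials),
    config = cfg[setdiff(names(cfg), "labels")],
    labels = cfg$labels,
    true_weights = attr(trials, "true_weights")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated trial set back from a directory
#'
#' @param dir Directory written by [write_trial_set()].
#' @return A `trial_set`.
#' @export
read_trial_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  tw <- man$true_weights
  trials <- purrr::map(seq_len(man$n_trials), function(k) {
    structure(
      list(eeg = read_eeg_csv(file.path(dir, sprintf("trial%d_eeg.csv", k))),
           kin = read_kin_csv(file.path(dir, sprintf("trial%d_kin.csv", k))),
           eog = read_timestamped_csv(file.path(dir, sprintf("trial%d_eog.csv", k)), "EOG"),
           true_weights = tw,
           config = c(man$config, list(labels = man$labels))),
      class = "synthetic_trial")
  })
  structure(trials, class = "trial_set", true_weights = tw,
            config = c(man$config, list(labels = man$labels)))
}

#' Serialize fitted decoders to JSON
#'
#' Full double precision is kept so a write/read round trip reproduces the
#' model exactly.
#'
#' @param model An `mlr_decoder` or `pf_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  payload <- if (inherits(model, "mlr_decoder")) {
    list(type = "mlr", intercepts = model$intercepts,
         weights = model$weights, n_lags = model$n_lags,
         channel_labels = model$channel_labels,
         coord_labels = model$coord_labels,
         train_norm = model$train_norm)
  } else if (inherits(model, "pf_model")) {
    list(type = "pf", A = model$state$A, Q = model$state$Q, d = model$state$d,
         H = model$meas$H, sigma2 = model$meas$sigma2,
         channel_labels = model$meas$channel_labels,
         coord_labels = model$coord_labels,
         train_kin = model$train_kin, train_norm = model$train_norm)
  } else {
    abort("unsupported model class")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(p$type, "mlr")) {
    w <- p$weights
    if (!is.array(w)) w <- array(unlist(w), dim = c(length(p$channel_labels),
                                                    p$n_lags + 1,
                                                    length(p$intercepts)))
    structure(
      list(intercepts = as.numeric(p$intercepts), weights = w,
           n_lags = p$n_lags, channel_labels = p$channel_labels,
           coord_labels = p$coord_labels,
           train_norm = p$train_norm, r_train = NA_real_),
      class = "mlr_decoder")
  } else if (identical(p$type, "pf")) {
    d <- p$d
    structure(
      list(state = structure(list(A = as.matrix(p$A), Q = as.matrix(p$Q),
                                  d = d), class = "state_model"),
           meas = structure(list(H = as.matrix(p$H),
                                 sigma2 = as.numeric(p$sigma2),
                                 m = length(p$sigma2), d = d,
                                 channel_labels = p$channel_labels),
                            class = "measurement_model"),
           train_kin = as.matrix(p$train_kin),
           train_norm = list(mean = as.numeric(p$train_norm$mean),
                             sd = as.numeric(p$train_norm$sd)),
           coord_labels = p$coord_labels),
      class = "pf_model")
  } else {
    abort(paste0("unknown model type in ", path))
  }
}

#' Load a run configuration from YAML or JSON
#'
#' Recognized keys are the fields of [forward_model_config()],
#' [preprocess_config()] and [pf_config()] plus `decoder`, `lags`, and
#' `seed`; unknown keys are rejected with a message listing them.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list of validated configuration values.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- unique(c(
    names(formals(forward_model_config)),
    names(formals(preprocess_config)),
    names(formals(pf_config)),
    "decoder", "lags", "seed"
  ))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  raw
}
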