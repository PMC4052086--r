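# Scoring and experiment designs: Pearson correlation between measured and
# reconstructed positions, leave-one-trial-out cross-validation,
# single-electrode contribution maps, training-size curves, data-length and
# high-frequency robustness studies. Experiment functions take a trial_set
# and return tidy tibbles (one row per fold / condition).

#' Pearson correlation between two series
#'
#' The accuracy metric for trajectory reconstruction. Pairs containing
#' non-finite values (e.g. the invalid lag window of a linear-decoder
#' prediction) are dropped before computing.
#'
#' @param x,y Numeric vectors of equal length (>= 3 finite pairs), neither
#'   constant.
#' @return Sample correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) abort("need at least 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("cannot correlate a constant series")
  cor(x, y)
}

# Per-dimension r between a predicted and a measured kinematics tibble,
# excluding burn-in samples.
score_prediction <- function(pred, truth, burn_in = 0) {
  dims <- channel_names(truth)
  keep <- seq_len(min(nrow(pred), nrow(truth)))
  keep <- keep[keep > burn_in]
  vapply(dims, function(dd) pearson_r(pred[[dd]][keep], truth[[dd]][keep]),
         numeric(1))
}

preprocess_trials <- function(trials, pp_config, use_eog = TRUE) {
  purrr::map(trials, function(tr) {
    run_pipeline(tr$eeg, tr$kin, pp_config,
                 veog = if (use_eog) tr$eog$veog,
                 heog = if (use_eog) tr$eog$heog)
  })
}

decode_fold <- function(train, test, decoder, L, pf_cfg, pf_burn_in) {
  if (decoder == "mlr") {
    model <- fit_mlr(purrr::map(train, "eeg"), purrr::map(train, "kin"), L)
    pred <- predict_mlr(model, test$eeg)
    burn <- L
  } else {
    model <- fit_pf(train[[1]]$eeg, train[[1]]$kin)
    pred <- predict(model, test$eeg, config = pf_cfg)
    burn <- pf_burn_in
  }
  list(pred = pred, r = score_prediction(pred, test$kin, burn_in = burn))
}

#' Leave-one-trial-out cross-validation of a decoder
#'
#' Each trial serves once as the test set while the rest train (6 folds
#' for 6 trials). The linear decoder trains on all remaining trials
#' (design matrices stacked per trial); the particle filter trains on a
#' single trial — the first remaining one, or, with `pf_train_trial` set,
#' that fixed trial trains once and every other trial is tested against it
#' (single-training-trial mode, giving `n - 1` results).
#'
#' @param trials A `trial_set`.
#' @param decoder `"mlr"` or `"pf"`.
#' @param L Lags for the linear decoder.
#' @param pf_cfg A [pf_config()] for the particle filter.
#' @param pp_config A [preprocess_config()] applied to every trial.
#' @param pf_train_trial Optional trial index for single-training mode.
#' @param pf_burn_in Particle-filter samples excluded from scoring while
#'   the posterior settles.
#' @param keep_predictions Attach predictions as a list-column.
#' @return Tibble of class `cv_result`: one row per fold x dimension with
#'   `decoder`, `test_trial`, `dim`, `r`.
#' @export
cross_validate <- function(trials, decoder = c("mlr", "pf"), L = 2,
                           pf_cfg = pf_config(), pp_config = preprocess_config(),
                           pf_train_trial = NULL, pf_burn_in = 5,
                           keep_predictions = FALSE) {
  decoder <- match.arg(decoder)
  if (length(trials) < 2) abort("cross-validation needs at least 2 trials")
  prepped <- preprocess_trials(trials, pp_config)
  if (decoder == "pf" && !is.null(pf_train_trial)) {
    folds <- setdiff(seq_along(prepped), pf_train_trial)
    train_sets <- purrr::map(folds, ~ prepped[pf_train_trial])
  } else {
    folds <- seq_along(prepped)
    train_sets <- purrr::map(folds, ~ prepped[-.x])
  }
  rows <- purrr::map2(folds, train_sets, function(test_idx, train) {
    res <- decode_fold(train, prepped[[test_idx]], decoder, L, pf_cfg,
                       pf_burn_in)
    out <- tibble::tibble(
      decoder = decoder, test_trial = test_idx,
      dim = names(res$r), r = as.numeric(res$r))
    if (keep_predictions) {
      out$prediction <- purrr::map(seq_len(nrow(out)), ~ res$pred)
      out$measured <- purrr::map(seq_len(nrow(out)), ~ prepped[[test_idx]]$kin)
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cv_result", class(out))
  out
}

#' Single-electrode contribution map
#'
#' Re-runs the chosen decoder with one electrode at a time: the decoder is
#' trained on one designated trial from that electrode alone and verified
#' on every other trial; the test correlation, averaged over held-out
#' trials and coordinates, is the electrode's contribution. Averaging over
#' several held-out trials matters: slow EEG background and slow movements
#' share so few effective cycles per trial that single-trial correlations
#' from uninformative electrodes are far from zero.
#'
#' @inheritParams cross_validate
#' @param train_trial Index of the training trial.
#' @return Tibble of class `contribution_map` with `channel`, `r`,
#'   `decoder`.
#' @export
electrode_contribution <- function(trials, decoder = c("mlr", "pf"), L = 2,
                                   pf_cfg = pf_config(),
                                   pp_config = preprocess_config(),
                                   train_trial = 1) {
  decoder <- match.arg(decoder)
  prepped <- preprocess_trials(trials, pp_config)
  tests <- setdiff(seq_along(prepped), train_trial)
  chans <- channel_names(prepped[[1]]$eeg)
  rows <- purrr::map(chans, function(ch) {
    sub <- function(tr) list(eeg = tr$eeg[c("time", ch)], kin = tr$kin)
    train <- list(sub(prepped[[train_trial]]))
    rs <- vapply(tests, function(j) {
      mean(decode_fold(train, sub(prepped[[j]]), decoder, L, pf_cfg, 5)$r)
    }, numeric(1))
    tibble::tibble(channel = ch, r = mean(rs))
  })
  out <- dplyr::bind_rows(rows)
  out$decoder <- decoder
  class(out) <- c("contribution_map", class(out))
  out
}

#' Decoding accuracy as a function of training-set size
#'
#' For each n in `1..max_n`, draws `repeats` random training subsets
#' (seeded), trains the decoder, and tests on a held-out trial never used
#' for training; reports the mean and SD of the test correlation (averaged
#' over coordinates).
#'
#' @inheritParams cross_validate
#' @param max_n Largest training-set size (must leave at least one trial
#'   for testing).
#' @param repeats Random subsets per size.
#' @param seed Master seed for subset draws.
#' @param sizes Training-set sizes to evaluate (defaults to `1..max_n`);
#'   a subset, e.g. `c(1, 5)`, compares just the endpoints of the curve.
#' @return Tibble of class `training_curve` with `n_train`, `mean_r`,
#'   `sd_r`.
#' @export
training_size_curve <- function(trials, decoder = c("mlr", "pf"),
                                max_n = length(trials) - 1, repeats = 3,
                                seed = 1, L = 2, pf_cfg = pf_config(),
                                pp_config = preprocess_config(),
                                sizes = seq_len(max_n)) {
  decoder <- match.arg(decoder)
  if (max_n >= length(trials)) {
    abort("max_n must leave at least one trial for testing")
  }
  if (any(sizes < 1 | sizes > max_n)) abort("sizes must lie in 1..max_n")
  prepped <- preprocess_trials(trials, pp_config)
  set.seed(derive_seed(seed, "training-size"))
  # paired nested design: within a repeat the test trial is fixed and the
  # size-n training set is the first n of one shuffled pool, so the only
  # thing changing along the curve is how much data the decoder sees
  per_rep <- purrr::map(seq_len(repeats), function(rep) {
    test_idx <- sample(seq_along(prepped), 1)
    pool <- sample(setdiff(seq_along(prepped), test_idx))
    vapply(sizes, function(n) {
      res <- decode_fold(prepped[pool[seq_len(n)]], prepped[[test_idx]],
                         decoder, L, pf_cfg, 5)
      mean(res$r)
    }, numeric(1))
  })
  rs <- do.call(rbind, per_rep) # repeats x length(sizes)
  out <- tibble::tibble(
    n_train = sizes,
    mean_r = colMeans(rs),
    sd_r = apply(rs, 2, sd)
  )
  class(out) <- c("training_curve", class(out))
  out
}

#' Decoding accuracy as a function of trial length
#'
#' Generates a fresh two-trial set (train + test) for each requested
#' length, runs the particle filter, and reports the mean test correlation
#' per length. Whether an intermediate length wins depends on the data;
#' no particular optimum is asserted.
#'
#' @param trial_lengths_s Trial durations in seconds.
#' @param config A [forward_model_config()].
#' @param kind,rate Trajectory kind and rate (see [generate_trajectory()]).
#' @param pf_cfg,pp_config Decoder and preprocessing configuration.
#' @return Tibble with `length_s` and `mean_r`.
#' @export
data_length_experiment <- function(trial_lengths_s,
                                   config = forward_model_config(),
                                   kind = "spiral2d", rate = 64,
                                   pf_cfg = pf_config(),
                                   pp_config = preprocess_config()) {
  if (any(trial_lengths_s <= 0)) abort("trial lengths must be positive")
  rows <- purrr::map(trial_lengths_s, function(len) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("len", len))
    ts <- make_trial_set(2, kind, len, rate, cfg)
    res <- cross_validate(ts, "pf", pf_cfg = pf_cfg, pp_config = pp_config,
                          pf_train_trial = 1)
    tibble::tibble(length_s = len, mean_r = mean(res$r))
  })
  dplyr::bind_rows(rows)
}

#' High-frequency robustness of the two decoders
#'
#' Decodes trials that carry strong above-2 Hz EEG content twice per
#' decoder: once through the full chain including the 2 Hz low-pass, once
#' with the low-pass stage disabled. Reports the correlation pair, the
#' drop (filtered minus unfiltered), and the above-2 Hz band power of the
#' unfiltered-mode reconstruction (the linear decoder passes the
#' contamination straight into its output; the particle filter's motion
#' prior smooths it away).
#'
#' @inheritParams cross_validate
#' @return Tibble of class `hf_robustness` with one row per decoder:
#'   `decoder`, `r_filtered`, `r_unfiltered`, `drop`, `pred_hf_power`.
#' @export
highfreq_robustness <- function(trials, L = 2, pf_cfg = pf_config(),
                                pp_config = preprocess_config()) {
  cfg_nolp <- pp_config
  cfg_nolp$lowpass_cutoff <- NULL
  run_one <- function(decoder, pp) {
    prepped <- preprocess_trials(trials, pp)
    n <- length(prepped)
    train <- if (decoder == "pf") prepped[1] else prepped[-n]
    res <- decode_fold(train, prepped[[n]], decoder, L, pf_cfg, 5)
    res
  }
  rows <- purrr::map(c("mlr", "pf"), function(dec) {
    filt <- run_one(dec, pp_config)
    unfi <- run_one(dec, cfg_nolp)
    tibble::tibble(
      decoder = dec,
      r_filtered = mean(filt$r),
      r_unfiltered = mean(unfi$r),
      drop = mean(filt$r) - mean(unfi$r),
      pred_hf_power = mean(vapply(channel_names(unfi$pred), function(dd) {
        band_power_above(unfi$pred[[dd]], signal_rate(unfi$pred), 2)
      }, numeric(1)))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hf_robustness", class(out))
  out
}

#' Fraction-free band power above a frequency
#'
#' Periodogram power of a series integrated above `f0` Hz, used for
#' spectral contracts (drift below 0.05 Hz, high-frequency band above
#' 2 Hz) and for comparing reconstruction smoothness.
#'
#' @param x Numeric series (non-finite values dropped).
#' @param rate Sampling rate in Hz.
#' @param f0 Band edge in Hz.
#' @return Summed periodogram power above `f0`.
#' @export
band_power_above <- function(x, rate, f0) {
  x <- x[is.finite(x)]
  x <- x - mean(x)
  sp <- Mod(fft(x))^2
  n <- length(x)
  freq <- (seq_len(n) - 1) * rate / n
  half <- freq <= rate / 2
  sum(sp[half & freq > f0]) / n
}

#' @rdname band_power_above
#' @export
band_power_fraction_below <- function(x, rate, f0) {
  x <- x[is.finite(x)]
  x <- x - mean(x)
  sp <- Mod(fft(x))^2
  n <- length(x)
  freq <- (seq_len(n) - 1) * rate / n
  half <- freq <= rate / 2
  sum(sp[half & freq <= f0]) / sum(sp[half])
}
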