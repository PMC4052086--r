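# Small programmatic fixtures shared across test files.

# EEG tibble with given channel signals (list of numeric vectors)
make_eeg <- function(signals, rate = 100, t0 = 0,
                     labels = paste0("CH", seq_along(signals))) {
  n <- length(signals[[1]])
  df <- tibble::tibble(time = t0 + (seq_len(n) - 1) / rate)
  for (i in seq_along(signals)) df[[labels[i]]] <- signals[[i]]
  df
}

make_kin2d <- function(x, y, rate = 64, t0 = 0) {
  tibble::tibble(time = t0 + (seq_along(x) - 1) / rate, x = x, y = y)
}

# amplitude of the f-Hz component of x via sin/cos regression
fit_amplitude <- function(x, f, rate) {
  tt <- (seq_along(x) - 1) / rate
  X <- cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
  cf <- qr.solve(X, x)
  sqrt(sum(cf^2))
}

# noiseless forward config shared by exact-recovery tests
clean_config <- function(...) {
  forward_model_config(noise_sd = 0, drift_amp = 0, eog_gain = 0, hf_amp = 0,
                       ...)
}

quiet_pp <- function(trial, config = preprocess_config(), eog = TRUE) {
  run_pipeline(trial$eeg, trial$kin, config,
               veog = if (eog) trial$eog$veog,
               heog = if (eog) trial$eog$heog)
}

# 1/f-shaped noise series for building EEG-like test channels
pink_noise_series <- function(n) eegdecode:::pink_noise(n)
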