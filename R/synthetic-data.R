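# Synthetic forward model: known 2D/3D trajectories encoded into
# EEG-like multichannel signals through lagged linear weights, on top of a
# pink-noise background with baseline drift, ocular (EOG) leakage and a
# high-frequency band. Because the encoding weights are known, decoders can
# be validated by parameter and trajectory recovery.

#' Configuration of the synthetic EEG forward model
#'
#' Defaults emulate a 30-channel, 500 Hz scalp recording in which every
#' channel carries trajectory information through 4 encoding lags, with a
#' per-channel pink-noise background whose amplitude roughly matches the
#' encoded signal, a slow baseline drift, moderate EOG coupling, and a
#' 5-40 Hz high-frequency band.
#'
#' @param n_channels Number of EEG channels (10-20 labels assigned in
#'   montage order, starting FP1, FP2, ...).
#' @param n_informative Number of channels that carry trajectory signal;
#'   the remainder are pure background. Informative channels are the first
#'   `n_informative` channels after FP1/FP2 (which real pipelines drop),
#'   unless `informative_channels` is given.
#' @param informative_channels Optional integer indices (into the montage)
#'   of the informative channels, overriding the default placement.
#' @param lags Number of encoding lags L (at the EEG rate); each informative
#'   channel mixes position samples at lags 0..L.
#' @param eeg_rate EEG sampling rate in Hz.
#' @param noise_sd Pink-noise standard deviation per channel, on the scale
#'   of the standardized encoded signal.
#' @param drift_amp Amplitude of a slow (< 0.05 Hz) sinusoidal baseline
#'   drift added per channel.
#' @param eog_gain Coupling strength of the simulated VEOG/HEOG traces into
#'   the EEG channels (scaled per channel).
#' @param hf_amp Standard deviation of an added 5-40 Hz band.
#' @param seed RNG seed; every generated quantity is a pure function of it.
#' @return A list of class `forward_model_config`.
#' @export
forward_model_config <- function(n_channels = 30, n_informative = n_channels,
                                 informative_channels = NULL,
                                 lags = 3, eeg_rate = 500,
                                 noise_sd = 3, drift_amp = 2, eog_gain = 0.5,
                                 hf_amp = 1, seed = 1) {
  if (n_informative > n_channels) {
    abort("n_informative must not exceed n_channels")
  }
  if (any(c(noise_sd, drift_amp, eog_gain, hf_amp) < 0)) {
    abort("noise_sd, drift_amp, eog_gain and hf_amp must all be >= 0")
  }
  if (lags < 0) abort("lags must be >= 0")
  labels <- montage_10_20(n_channels)
  if (is.null(informative_channels)) {
    pool <- c(setdiff(seq_len(n_channels), match(c("FP1", "FP2"), labels)),
              match(c("FP1", "FP2"), labels))
    pool <- pool[!is.na(pool)]
    informative_channels <- sort(pool[seq_len(n_informative)])
  }
  if (length(informative_channels) != n_informative ||
      any(informative_channels < 1 | informative_channels > n_channels)) {
    abort("informative_channels must be n_informative valid channel indices")
  }
  structure(
    list(n_channels = n_channels, n_informative = n_informative,
         informative_channels = informative_channels, lags = lags,
         eeg_rate = eeg_rate, noise_sd = noise_sd, drift_amp = drift_amp,
         eog_gain = eog_gain, hf_amp = hf_amp, seed = seed,
         labels = labels),
    class = "forward_model_config"
  )
}

# 1/f ("pink") noise via spectral shaping of seeded white noise,
# normalized to unit standard deviation.
pink_noise <- function(n) {
  w <- rnorm(n)
  sp <- fft(w)
  freq_bin <- c(1, seq_len(n - 1)) # avoid dividing DC by zero
  freq_bin <- pmin(freq_bin, n - freq_bin + 1) # symmetric shaping
  shaped <- Re(fft(sp / sqrt(freq_bin), inverse = TRUE)) / n
  as.numeric(scale(shaped))
}

# Band-limited noise: white noise filtered to [lo, hi] Hz, unit sd.
band_noise <- function(n, rate, lo, hi) {
  ny <- rate / 2
  bf <- signal::butter(4, c(lo, min(hi, 0.95 * ny)) / ny, type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  s <- sd(x)
  if (s == 0) return(x)
  x / s
}

# Blink-like VEOG (sparse positive bumps) and saccade-like HEOG (smoothed
# step process), both at the EEG rate, unit-scale amplitudes.
simulate_eog <- function(n, rate) {
  tt <- (seq_len(n) - 1) / rate
  veog <- numeric(n)
  n_blinks <- max(1L, round(n / rate / 5)) # roughly one blink per 5 s
  centers <- runif(n_blinks, min = 0.5, max = max(tt) - 0.5)
  for (ct in centers) veog <- veog + 5 * exp(-((tt - ct) / 0.07)^2)
  n_sac <- max(2L, round(n / rate / 2))
  lv <- cumsum(rnorm(n_sac))
  heog <- approx(seq(0, max(tt), length.out = n_sac), lv, xout = tt,
                 method = "constant", rule = 2)$y
  bf <- signal::butter(2, min(0.45, 8 / (rate / 2)), type = "low")
  heog <- signal::filtfilt(bf, heog)
  list(veog = veog, heog = 2 * heog)
}

#' Generate a reference hand trajectory
#'
#' `spiral2d` reproduces a cursor-tracking paradigm: an Archimedean spiral
#' traversed at constant angular rate (0.1 turns per second), so the
#' movement bandwidth stays well below 2 Hz. `free3d` emulates slow free
#' swinging: Gaussian noise low-passed below 1 Hz. Both are
#' amplitude-normalized to `[-1, 1]` per coordinate.
#'
#' @param kind `"spiral2d"` or `"free3d"`.
#' @param duration_s Duration in seconds.
#' @param rate Sampling rate in Hz (64 Hz for the tracked cursor, 120 Hz
#'   for optical hand tracking).
#' @param seed RNG seed (used by `free3d`; the spiral is deterministic).
#' @return A tibble with columns `time`, `x`, `y` (and `z` for `free3d`),
#'   `floor(duration_s * rate)` rows.
#' @export
#' @examples
#' generate_trajectory("spiral2d", duration_s = 8, rate = 64, seed = 1)
generate_trajectory <- function(kind = c("spiral2d", "free3d"),
                                duration_s, rate, seed = 1) {
  kind <- match.arg(kind)
  if (duration_s <= 0 || rate <= 0) abort("duration_s and rate must be > 0")
  n <- floor(duration_s * rate)
  tt <- (seq_len(n) - 1) / rate
  if (kind == "spiral2d") {
    theta <- 2 * pi * 0.1 * tt # constant angular rate, 0.1 turns/s
    radius <- theta / max(theta) # Archimedean: radius proportional to angle
    pos <- cbind(radius * cos(theta), radius * sin(theta))
    # the recorded positions are the hand, not the cursor: add a small
    # smooth per-trial tracking error (< 1 Hz, 5% of the amplitude)
    set.seed(derive_seed(seed, "tracking-error"))
    bf <- signal::butter(4, min(0.8, 0.45 * rate) / (rate / 2), type = "low")
    err <- vapply(1:2, function(i) {
      e <- signal::filtfilt(bf, rnorm(n))
      0.05 * e / sd(e)
    }, numeric(n))
    pos <- pos + err
  } else {
    set.seed(derive_seed(seed, "free3d"))
    ny <- rate / 2
    bf <- signal::butter(4, 0.8 / ny, type = "low")
    pos <- vapply(1:3, function(i) signal::filtfilt(bf, rnorm(n)),
                  numeric(n))
  }
  pos <- apply(pos, 2, function(p) {
    p <- p - mean(p)
    p / max(abs(p))
  })
  new_kin(tt, pos)
}

#' Encode a trajectory into synthetic multichannel EEG
#'
#' Upsamples the trajectory to the EEG rate, standardizes it, and gives
#' each informative channel a lagged linear mixture of the coordinates with
#' standard-normal weights. Pink noise, a slow baseline drift, EOG leakage
#' and a 5-40 Hz band are then added per channel with the amplitudes set in
#' `config`. The generating weights are returned so decoders can be checked
#' by recovery.
#'
#' @param kin Trajectory tibble from [generate_trajectory()].
#' @param config A [forward_model_config()].
#' @param true_weights Optional pre-drawn weight array
#'   `(n_channels, lags + 1, d)`; drawn from the seeded RNG when `NULL`.
#' @return A list of class `synthetic_trial` with elements `eeg` (tibble,
#'   `time` + one column per channel), `kin` (the input trajectory),
#'   `eog` (tibble `time`, `veog`, `heog` at the EEG rate),
#'   `true_weights`, and `config`.
#' @export
generate_eeg_from_kinematics <- function(kin, config, true_weights = NULL) {
  if (nrow(kin) == 0) abort("trajectory has zero length")
  kin_rate <- signal_rate(kin)
  if (kin_rate > config$eeg_rate) {
    abort("trajectory rate must not exceed the EEG rate")
  }
  set.seed(derive_seed(config$seed, "forward-model"))
  P <- as_channel_matrix(kin)
  d <- ncol(P)
  L <- config$lags
  nch <- config$n_channels

  n_eeg <- round(nrow(kin) * config$eeg_rate / kin_rate)
  t_eeg <- kin$time[1] + (seq_len(n_eeg) - 1) / config$eeg_rate
  Pz <- vapply(seq_len(d), function(j) {
    up <- spline(kin$time, P[, j], xout = t_eeg)$y
    (up - mean(up)) / sd(up)
  }, numeric(n_eeg))

  if (is.null(true_weights)) {
    true_weights <- array(0, dim = c(nch, L + 1, d))
    for (ch in config$informative_channels) {
      true_weights[ch, , ] <- rnorm((L + 1) * d)
    }
  }

  # lagged mixture; the first L samples reuse the first position sample
  Ppad <- if (L > 0) rbind(matrix(Pz[1, ], L, d, byrow = TRUE), Pz) else Pz
  eeg <- matrix(0, n_eeg, nch)
  for (ch in config$informative_channels) {
    acc <- numeric(n_eeg)
    for (k in 0:L) {
      lagged <- Ppad[(L + 1 - k):(L + n_eeg - k), , drop = FALSE]
      acc <- acc + lagged %*% true_weights[ch, k + 1, ]
    }
    eeg[, ch] <- acc
  }

  eog <- simulate_eog(n_eeg, config$eeg_rate)
  v_gain <- runif(nch, 0.2, 1) * config$eog_gain
  h_gain <- runif(nch, 0.2, 1) * config$eog_gain
  drift_f <- runif(nch, 0.01, 0.05)
  drift_ph <- runif(nch, 0, 2 * pi)
  # high-frequency artifacts (muscle, line interference) are shared
  # sources mixed into every channel, not independent sensor noise: they
  # do not average out across the montage
  if (config$hf_amp > 0) {
    n_src <- 3L
    hf_src <- vapply(seq_len(n_src),
                     function(i) band_noise(n_eeg, config$eeg_rate, 5, 40),
                     numeric(n_eeg))
    hf_gain <- matrix(rnorm(nch * n_src), nch, n_src)
    hf_gain <- hf_gain / sqrt(rowSums(hf_gain^2)) # unit per-channel hf sd
  }
  for (ch in seq_len(nch)) {
    extra <- numeric(n_eeg)
    if (config$noise_sd > 0) extra <- extra + config$noise_sd * pink_noise(n_eeg)
    if (config$drift_amp > 0) {
      extra <- extra +
        config$drift_amp * sin(2 * pi * drift_f[ch] * t_eeg + drift_ph[ch])
    }
    if (config$eog_gain > 0) {
      extra <- extra + v_gain[ch] * eog$veog + h_gain[ch] * eog$heog
    }
    if (config$hf_amp > 0) {
      extra <- extra + config$hf_amp * as.numeric(hf_src %*% hf_gain[ch, ])
    }
    eeg[, ch] <- eeg[, ch] + extra
  }

  structure(
    list(
      eeg = new_eeg(t_eeg, eeg, config$labels),
      kin = kin,
      eog = tibble::tibble(time = t_eeg, veog = eog$veog, heog = eog$heog),
      true_weights = true_weights,
      config = config
    ),
    class = "synthetic_trial"
  )
}

#' Generate a set of matched trials from one synthetic "subject"
#'
#' All trials share a single realization of the forward encoding weights
#' (one subject, one electrode/source geometry) but carry independent noise
#' (and, for `free3d`, independent trajectories). At least two trials are
#' required so cross-validation is possible.
#'
#' @inheritParams generate_trajectory
#' @param n_trials Number of trials (>= 2).
#' @param config A [forward_model_config()]; its `seed` is the master seed.
#' @return A list of class `trial_set` of `synthetic_trial` objects, with
#'   the shared weight array in `attr(, "true_weights")`.
#' @export
make_trial_set <- function(n_trials, kind = "spiral2d", duration_s = 48,
                           rate = 64, config = forward_model_config()) {
  if (n_trials < 2) {
    abort("need at least 2 trials (cross-validation is impossible with 1)")
  }
  set.seed(derive_seed(config$seed, "subject-weights"))
  d <- if (kind == "spiral2d") 2L else 3L
  L <- config$lags
  true_weights <- array(0, dim = c(config$n_channels, L + 1, d))
  for (ch in config$informative_channels) {
    true_weights[ch, , ] <- rnorm((L + 1) * d)
  }
  trials <- purrr::map(seq_len(n_trials), function(k) {
    cfg_k <- config
    cfg_k$seed <- derive_seed(config$seed, paste0("trial", k))
    traj <- generate_trajectory(kind, duration_s, rate,
                                seed = derive_seed(config$seed,
                                                   paste0("traj", k)))
    generate_eeg_from_kinematics(traj, cfg_k, true_weights = true_weights)
  })
  structure(trials, class = "trial_set", true_weights = true_weights,
            config = config)
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "<synthetic_trial> %d-channel EEG at %g Hz (%d samples), %dD kinematics at %g Hz (%d samples)\n",
    x$config$n_channels, x$config$eeg_rate, nrow(x$eeg),
    ncol(x$kin) - 1L, signal_rate(x$kin), nrow(x$kin)))
  invisible(x)
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials sharing one forward encoding\n", length(x)))
  invisible(x)
}
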