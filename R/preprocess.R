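# Preprocessing chain for continuous-movement EEG decoding:
# baseline-drift removal -> EOG artifact regression -> zero-phase low-pass
# -> anti-aliased resampling to the kinematics rate -> per-channel z-score.
# All operations take a timestamped tibble (time + one column per channel)
# and return one, so stages chain with the pipe.

#' Preprocessing configuration
#'
#' @param lowpass_cutoff Low-pass cut-off in Hz (2 Hz keeps the
#'   sub-movement band; hand movements live below 2 Hz). `NULL` disables
#'   the low-pass stage.
#' @param filter_order Butterworth order (5 by convention here).
#' @param drop_labels Channels removed before decoding; the most frontal
#'   electrodes FP1/FP2 are blink-dominated.
#' @param drift_method `"detrend_linear"` (least-squares line removal) or
#'   `"highpass"` (0.05 Hz zero-phase high-pass).
#' @param zscore Standardize channels and coordinates after resampling.
#' @return List of class `preprocess_config`.
#' @export
preprocess_config <- function(lowpass_cutoff = 2, filter_order = 5,
                              drop_labels = c("FP1", "FP2"),
                              drift_method = c("detrend_linear", "highpass"),
                              zscore = TRUE) {
  drift_method <- match.arg(drift_method)
  if (!is.null(lowpass_cutoff) && lowpass_cutoff <= 0) {
    abort("lowpass_cutoff must be positive (or NULL to disable)")
  }
  if (filter_order < 1) abort("filter_order must be >= 1")
  structure(list(lowpass_cutoff = lowpass_cutoff, filter_order = filter_order,
                 drop_labels = drop_labels, drift_method = drift_method,
                 zscore = zscore),
            class = "preprocess_config")
}

# Zero-phase filtering with odd-reflection padding. signal::filtfilt runs
# the filter forward and backward but starts from zero state, which leaves
# long edge transients for low cut-offs; reflecting the signal (odd
# symmetry about each endpoint) gives the filter a continuous run-in. The
# channel mean is removed first and restored afterwards when the filter
# passes DC, so constants go through exactly.
filt_zero_phase <- function(bf, x, pad_len, restore_mean = TRUE) {
  n <- length(x)
  mu <- mean(x)
  y <- x - mu
  p <- min(pad_len, n - 1)
  ext <- if (p > 0) {
    c(2 * y[1] - y[(p + 1):2], y, 2 * y[n] - y[(n - 1):(n - p)])
  } else {
    y
  }
  z <- signal::filtfilt(bf, ext)[(p + 1):(p + n)]
  if (restore_mean) z + mu else z
}

apply_channels <- function(eeg, f) {
  chans <- channel_names(eeg)
  out <- eeg
  for (ch in chans) out[[ch]] <- f(eeg[[ch]], ch)
  check_finite(out[chans], "preprocessed channels")
  out
}

#' Remove slow baseline drift from each channel
#'
#' DC-coupled amplifiers accumulate slow baseline drift; either a
#' least-squares line is subtracted per channel (`detrend_linear`) or a
#' 0.05 Hz 2nd-order zero-phase Butterworth high-pass is applied.
#'
#' @param eeg Tibble `time` + channels.
#' @param method `"detrend_linear"` or `"highpass"`.
#' @return Tibble of the same shape.
#' @export
remove_baseline_drift <- function(eeg, method = c("detrend_linear", "highpass")) {
  method <- match.arg(method)
  if (nrow(eeg) < 2) abort("need at least 2 samples to remove drift")
  tt <- eeg$time
  if (method == "detrend_linear") {
    X <- cbind(1, tt - mean(tt))
    apply_channels(eeg, function(x, ch) {
      x - X %*% lstsq_min_norm(X, x)
    })
  } else {
    rate <- signal_rate(eeg)
    bf <- signal::butter(2, 0.05 / (rate / 2), type = "high")
    if (nrow(eeg) < 12) abort("recording too short for the 0.05 Hz high-pass")
    pad <- round(3 * rate / 0.05)
    apply_channels(eeg, function(x, ch) {
      filt_zero_phase(bf, x, pad, restore_mean = FALSE)
    })
  }
}

#' Regress ocular artifacts out of every EEG channel
#'
#' Each channel is regressed (OLS with intercept) on the vertical and
#' horizontal EOG traces; the EOG-explained part is subtracted. Residuals
#' are exactly orthogonal to both regressors.
#'
#' @param eeg Tibble `time` + channels.
#' @param veog,heog Numeric vectors, same length and rate as the EEG.
#' @return Tibble of the same shape.
#' @export
regress_out_eog <- function(eeg, veog, heog) {
  n <- nrow(eeg)
  if (length(veog) != n || length(heog) != n) {
    abort("veog/heog must have the same length as the EEG")
  }
  X <- cbind(intercept = 1, VEOG = veog, HEOG = heog)
  qrX <- qr(X)
  if (qrX$rank < 3) {
    bad <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    abort(paste0("EOG regressors are collinear (degenerate: ",
                 paste(bad, collapse = ", "), ")"))
  }
  apply_channels(eeg, function(x, ch) qr.resid(qrX, x))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward filtering doubles the attenuation (the effective
#' amplitude response is the squared one-pass magnitude) and cancels the
#' phase lag, so the lag structure between EEG and kinematics is preserved.
#' A one-pass causal filter is available for completeness.
#'
#' @param eeg Tibble `time` + channels.
#' @param cutoff Cut-off frequency in Hz (must be below Nyquist).
#' @param order Filter order.
#' @param zero_phase Forward-backward (default) or one-pass causal.
#' @return Tibble of the same shape.
#' @export
lowpass_filter <- function(eeg, cutoff = 2, order = 5, zero_phase = TRUE) {
  rate <- signal_rate(eeg)
  if (cutoff >= rate / 2) {
    abort(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)",
                  cutoff, rate / 2))
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  if (zero_phase) {
    pad <- round(3 * rate / cutoff)
    apply_channels(eeg, function(x, ch) filt_zero_phase(bf, x, pad))
  } else {
    apply_channels(eeg, function(x, ch) {
      as.numeric(signal::filter(bf, x))
    })
  }
}

#' Resample a recording to a target rate
#'
#' Anti-aliased band-limited resampling: when downsampling, an 8th-order
#' zero-phase Butterworth at 90% of the target Nyquist removes energy that
#' would alias; samples at the new timestamps are then obtained by cubic
#' spline interpolation. Sub-2 Hz content is preserved to well below 1e-3
#' relative error away from the edges.
#'
#' @param eeg Tibble `time` + channels (also works for kinematics).
#' @param target_rate Target rate in Hz.
#' @return Tibble at the new rate with `round(n * target / rate)` rows.
#' @export
resample_to <- function(eeg, target_rate) {
  if (target_rate <= 0) abort("target_rate must be > 0")
  rate <- signal_rate(eeg)
  if (isTRUE(all.equal(rate, target_rate))) return(eeg)
  n_out <- round(nrow(eeg) * target_rate / rate)
  t_out <- eeg$time[1] + (seq_len(n_out) - 1) / target_rate
  work <- eeg
  if (target_rate < rate) {
    cutoff <- 0.45 * target_rate
    bf <- signal::butter(8, cutoff / (rate / 2), type = "low")
    pad <- round(3 * rate / cutoff)
    work <- apply_channels(work, function(x, ch) filt_zero_phase(bf, x, pad))
  }
  out <- purrr::map(channel_names(work), function(ch) {
    spline(work$time, work[[ch]], xout = t_out)$y
  })
  names(out) <- channel_names(work)
  dplyr::bind_cols(tibble::tibble(time = t_out), tibble::as_tibble(out))
}

#' Standardize channels to zero mean and unit standard deviation
#'
#' `normalize(x) = (x - mean(x)) / sd(x)` applied per channel. The same
#' transform standardizes kinematics coordinates. For a plain matrix the
#' convention is channels-by-samples, i.e. rows are standardized.
#'
#' @param x Tibble (`time` + channels) or numeric matrix (channels x
#'   samples).
#' @return Object of the same shape.
#' @export
zscore_channels <- function(x) {
  zs <- function(v, label) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      abort(paste0("cannot z-score constant channel ", label))
    }
    (v - mean(v)) / s
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1, function(r) zs(r, "row")))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  apply_channels(x, zs)
}

#' Trim two timestamped streams to their common time span
#'
#' @param eeg Tibble `time` + channels.
#' @param kin Tibble `time` + coordinates.
#' @return List with trimmed `eeg` and `kin`; after [resample_to()] at the
#'   kinematics rate their sample counts match.
#' @export
synchronize <- function(eeg, kin) {
  er <- signal_rate(eeg)
  kr <- signal_rate(kin)
  # a sample at t covers [t, t + 1/rate): spans have duration semantics
  start <- max(eeg$time[1], kin$time[1])
  end <- min(eeg$time[1] + nrow(eeg) / er, kin$time[1] + nrow(kin) / kr)
  if (start >= end) abort("EEG and kinematics time spans are disjoint")
  tol_e <- 0.5 / er
  tol_k <- 0.5 / kr
  eeg2 <- dplyr::filter(eeg, .data$time >= start - tol_e, .data$time < end - tol_e)
  kin2 <- dplyr::filter(kin, .data$time >= start - tol_k, .data$time < end - tol_k)
  # force counts consistent under round(n * kr / er)
  n_target <- round(nrow(kin2) * er / kr)
  if (nrow(eeg2) > n_target) eeg2 <- eeg2[seq_len(n_target), ]
  if (round(nrow(eeg2) * kr / er) < nrow(kin2)) {
    kin2 <- kin2[seq_len(round(nrow(eeg2) * kr / er)), ]
  }
  list(eeg = eeg2, kin = kin2)
}

#' Drop channels by label
#'
#' @param eeg Tibble `time` + channels.
#' @param labels Channel labels to remove; labels not present are ignored
#'   with a warning.
#' @return Tibble without the named channels, remaining order preserved.
#' @export
drop_channels <- function(eeg, labels) {
  chans <- channel_names(eeg)
  missing <- setdiff(labels, chans)
  if (length(missing) > 0) {
    warn(paste0("channels not present, ignored: ",
                paste(missing, collapse = ", ")))
  }
  keep <- setdiff(chans, labels)
  if (length(keep) == 0) abort("cannot drop all channels")
  eeg[c("time", keep)]
}

#' Run the full preprocessing chain on one trial
#'
#' Fixed stage order: channel exclusion and synchronization, then baseline
#' drift removal, EOG regression, low-pass, resampling to the kinematics
#' rate, and z-scoring of both streams. Each stage logs shapes via
#' [message()] when `verbose = TRUE`.
#'
#' @param eeg Tibble `time` + channels.
#' @param kin Tibble `time` + coordinates.
#' @param config A [preprocess_config()].
#' @param veog,heog Optional EOG traces (same rate/length as `eeg`); when
#'   `NULL` the EOG stage is skipped.
#' @param verbose Log each stage.
#' @return List with preprocessed `eeg` and `kin`, equal length, at the
#'   kinematics rate.
#' @export
run_pipeline <- function(eeg, kin, config = preprocess_config(),
                         veog = NULL, heog = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) inform(sprintf(...))
  if (length(config$drop_labels) > 0) {
    present <- intersect(config$drop_labels, channel_names(eeg))
    if (length(present) > 0) eeg <- drop_channels(eeg, present)
    say("drop_channels: %d channels remain", length(channel_names(eeg)))
  }
  eeg <- remove_baseline_drift(eeg, config$drift_method)
  say("drift removal (%s): %d x %d", config$drift_method,
      nrow(eeg), length(channel_names(eeg)))
  if (!is.null(veog) && !is.null(heog)) {
    eeg <- regress_out_eog(eeg, veog, heog)
    say("EOG regression done")
  }
  if (!is.null(config$lowpass_cutoff)) {
    eeg <- lowpass_filter(eeg, config$lowpass_cutoff, config$filter_order)
    say("low-pass %g Hz (order %d)", config$lowpass_cutoff, config$filter_order)
  }
  sync <- synchronize(eeg, kin)
  kr <- signal_rate(sync$kin)
  eeg <- resample_to(sync$eeg, kr)
  kin <- sync$kin
  n <- min(nrow(eeg), nrow(kin))
  eeg <- eeg[seq_len(n), ]
  kin <- kin[seq_len(n), ]
  say("resampled to %g Hz: %d samples", kr, n)
  if (isTRUE(config$zscore)) {
    eeg <- zscore_channels(eeg)
    kin <- zscore_channels(kin)
    say("z-scored channels and coordinates")
  }
  list(eeg = eeg, kin = kin)
}
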