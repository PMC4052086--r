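# Preprocessing chain: drift removal, EOG regression, filtering,
# resampling, z-scoring, synchronization, channel handling.

test_that("linear detrend removes ramps and leaves whole-period sinusoids alone", {
  rate <- 100
  n <- 4000 # 40 s: whole number of 1 Hz periods
  tt <- (seq_len(n) - 1) / rate
  eeg <- make_eeg(list(3 * tt + 2, cos(2 * pi * 1 * tt)), rate = rate)
  out <- remove_baseline_drift(eeg, "detrend_linear")
  expect_lt(max(abs(out$CH1)), 1e-10)
  expect_lt(max(abs(out$CH2 - eeg$CH2)), 1e-3 * max(abs(eeg$CH2)))
  # mean after removal is numerically zero relative to channel scale
  expect_lt(abs(mean(out$CH2)), 1e-9 * sd(out$CH2))
  expect_error(remove_baseline_drift(eeg[0, ]), "at least 2")
})

test_that("high-pass drift removal suppresses sub-0.05 Hz content", {
  rate <- 50
  tt <- (seq_len(3000) - 1) / rate
  slow <- sin(2 * pi * 0.01 * tt)
  fast <- sin(2 * pi * 1 * tt)
  out <- remove_baseline_drift(make_eeg(list(slow + fast), rate = rate),
                               "highpass")
  mid <- 500:2500
  expect_lt(sd(out$CH1[mid] - fast[mid]), 0.15 * sd(slow))
})

test_that("EOG regression is exact OLS with orthogonal residuals", {
  set.seed(1)
  n <- 1000
  tt <- (seq_len(n) - 1) / 100
  s <- sin(2 * pi * 0.7 * tt)
  s <- s - mean(s)
  orth <- function(v) { # orthogonalize an EOG trace against s and 1
    v <- v - mean(v)
    v - s * sum(v * s) / sum(s * s)
  }
  veog <- orth(rnorm(n))
  heog <- orth(rnorm(n))
  eeg <- make_eeg(list(s + 0.5 * veog, rnorm(n)), rate = 100)
  out <- regress_out_eog(eeg, veog, heog)
  # contaminated channel comes back as the clean signal
  expect_lt(max(abs(out$CH1 - s)) / sd(s), 1e-6)
  # residuals orthogonal to both EOG traces
  for (ch in c("CH1", "CH2")) {
    expect_lt(abs(sum(out[[ch]] * veog)),
              1e-6 * sqrt(sum(out[[ch]]^2) * sum(veog^2)))
    expect_lt(abs(sum(out[[ch]] * heog)),
              1e-6 * sqrt(sum(out[[ch]]^2) * sum(heog^2)))
  }
  expect_error(regress_out_eog(eeg, veog, veog), "collinear")
  expect_error(regress_out_eog(eeg, veog[-1], heog[-1]), "length")
})

test_that("channel orthogonal to the EOGs is untouched", {
  set.seed(2)
  n <- 500
  veog <- rnorm(n)
  heog <- rnorm(n)
  ch <- rnorm(n)
  X <- cbind(1, veog, heog)
  ch_perp <- as.numeric(qr.resid(qr(X), ch))
  out <- regress_out_eog(make_eeg(list(ch_perp), rate = 100), veog, heog)
  expect_lt(max(abs(out$CH1 - ch_perp)), 1e-9)
})

test_that("zero-phase Butterworth matches the analytic squared magnitude", {
  rate <- 500
  tt <- seq(0, 20 - 1 / rate, by = 1 / rate)
  gain2 <- function(f, fc, ord) (1 / (1 + (f / fc)^(2 * ord)))
  for (f in c(1, 10)) {
    eeg <- make_eeg(list(sin(2 * pi * f * tt)), rate = rate)
    out <- lowpass_filter(eeg, cutoff = 2, order = 5)
    mid <- tt > 6 & tt < 14
    amp <- fit_amplitude(out$CH1[mid], f, rate)
    expect_equal(amp, gain2(f, 2, 5), tolerance = 0.02)
  }
  # DC gain is unity
  dc <- lowpass_filter(make_eeg(list(rep(2.5, 2000)), rate = rate), 2, 5)
  expect_lt(max(abs(dc$CH1 - 2.5)), 1e-6)
  expect_error(lowpass_filter(make_eeg(list(tt), rate = rate), 300),
               "Nyquist")
})

test_that("zero-phase filtering has no phase lag; one-pass does", {
  rate <- 200
  tt <- seq(0, 30 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 0.5 * tt)
  eeg <- make_eeg(list(x), rate = rate)
  zp <- lowpass_filter(eeg, 2, 5, zero_phase = TRUE)$CH1
  op <- lowpass_filter(eeg, 2, 5, zero_phase = FALSE)$CH1
  mid <- 2000:4000
  lag_of <- function(y) {
    cc <- stats::ccf(y[mid], x[mid], lag.max = 100, plot = FALSE)
    cc$lag[which.max(cc$acf)]
  }
  expect_equal(lag_of(zp), 0)
  expect_gt(lag_of(op), 2)
})

test_that("resampling preserves in-band content and sample-count arithmetic", {
  rate <- 500
  tt <- seq(0, 48 - 1 / rate, by = 1 / rate)
  eeg <- make_eeg(list(sin(2 * pi * 1 * tt)), rate = rate)
  out <- resample_to(eeg, 64)
  expect_identical(nrow(out), 3072L)
  idx <- 200:(nrow(out) - 200)
  expect_lt(max(abs(out$CH1[idx] - sin(2 * pi * out$time[idx]))), 1e-3)
  out120 <- resample_to(eeg, 120)
  idx <- 500:(nrow(out120) - 500)
  expect_lt(max(abs(out120$CH1[idx] - sin(2 * pi * out120$time[idx]))), 1e-3)
  expect_identical(resample_to(eeg, 500), eeg)
  expect_error(resample_to(eeg, -5), "target_rate")
})

test_that("z-scoring is exact, idempotent, and rejects constants", {
  expect_equal(as.numeric(zscore_channels(matrix(c(1, 2, 3), 1))),
               c(-1, 0, 1))
  set.seed(3)
  M <- matrix(rnorm(50 * 200), 50)
  Z <- zscore_channels(M)
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-12)
  expect_lt(max(abs(zscore_channels(Z) - Z)), 1e-12)
  expect_error(zscore_channels(make_eeg(list(rep(1, 10)), labels = "PZ")),
               "PZ")
})

test_that("synchronization trims to the common span and matches counts", {
  rate_e <- 500
  rate_k <- 50
  eeg <- make_eeg(list(rnorm(10 * rate_e)), rate = rate_e, t0 = 0)
  kin <- make_kin2d(rnorm(9 * rate_k), rnorm(9 * rate_k), rate = rate_k,
                    t0 = 1)
  sync <- synchronize(eeg, kin)
  expect_gte(sync$eeg$time[1], 1 - 0.5 / rate_e)
  expect_identical(round(nrow(sync$eeg) * rate_k / rate_e),
                   as.double(nrow(sync$kin)))
  same <- synchronize(eeg, make_kin2d(rnorm(10 * rate_k), rnorm(10 * rate_k),
                                      rate = rate_k, t0 = 0))
  expect_identical(nrow(same$eeg), nrow(eeg))
  disj <- make_kin2d(rnorm(100), rnorm(100), rate = rate_k, t0 = 100)
  expect_error(synchronize(eeg, disj), "disjoint")
})

test_that("channel dropping preserves order and guards the montage", {
  eeg <- make_eeg(rep(list(rnorm(10)), 4), rate = 10,
                  labels = c("FP1", "FP2", "CZ", "PZ"))
  out <- drop_channels(eeg, c("FP1", "FP2"))
  expect_identical(names(out), c("time", "CZ", "PZ"))
  expect_identical(drop_channels(eeg, character(0)), eeg)
  expect_warning(drop_channels(eeg, c("CZ", "XX")), "XX")
  expect_error(suppressWarnings(
    drop_channels(eeg, c("FP1", "FP2", "CZ", "PZ"))), "all channels")
})

test_that("the full chain recovers an in-band signal buried in contamination", {
  cfg <- forward_model_config(n_channels = 5, n_informative = 5, lags = 0,
                              noise_sd = 0, drift_amp = 0, eog_gain = 0,
                              hf_amp = 3, eeg_rate = 500, seed = 21)
  ts <- make_trial_set(2, "spiral2d", 16, 64, cfg)
  pp <- quiet_pp(ts[[1]], preprocess_config(drop_labels = character(0)),
                 eog = FALSE)
  # each channel is w_x x + w_y y; reconstruct from the true weights and
  # push the clean mixture through the same linear in-band stages the
  # channels see (detrend + 2 Hz low-pass), leaving only the question of
  # whether the out-of-band contamination was removed
  w <- ts[[1]]$true_weights
  target <- as.numeric(scale(as.matrix(pp$kin[, c("x", "y")])) %*% w[1, 1, ])
  target <- stats::resid(stats::lm(target ~ pp$kin$time))
  target <- lowpass_filter(tibble::tibble(time = pp$kin$time, s = target),
                           2, 5)$s
  # away from the edges: the first/last 2 s carry filter edge transients
  mid <- 129:(length(target) - 128)
  expect_gt(abs(pearson_r(pp$eeg[[2]][mid], target[mid])), 0.999)
})
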