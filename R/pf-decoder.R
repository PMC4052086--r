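# Bayesian state-space decoder. The hidden state is the hand position; its
# temporal prior is a second-order linear motion model written in companion
# form over the augmented state [C_t; C_{t-1}],
#   C_{t+1} = A C_t + W,   W ~ N(0, Q),
# and the likelihood of the m-channel EEG sample given the position is a
# diagonal Gaussian (conditionally independent channels),
#   p(S_t | C_t) = (2*pi)^(-m/2) |Sigma|^(-1/2)
#                  exp(-1/2 (S_t - mu)' Sigma^-1 (S_t - mu)),
# with mu an affine function of the position fitted per channel by OLS.
# The posterior is tracked by sequential importance resampling and the
# decoded trajectory is the posterior mean sum_i w_i c_i at each step.

#' Particle filter configuration
#'
#' @param n_particles Number of particles N_s (>= 2).
#' @param seed RNG seed; the whole decode is deterministic given it.
#' @param resample `"every_step"` (unconditional, the default; the
#'   previous-step weight factor then cancels in the update) or
#'   `"ess_threshold"` (resample only when the effective sample size
#'   `1 / sum(w^2)` falls below `ess_fraction * n_particles`).
#' @param ess_fraction Threshold fraction for `"ess_threshold"` mode.
#' @return List of class `pf_config`.
#' @export
pf_config <- function(n_particles = 1000, seed = 1,
                      resample = c("every_step", "ess_threshold"),
                      ess_fraction = 0.5) {
  if (n_particles < 2) abort("n_particles must be >= 2")
  resample <- match.arg(resample)
  structure(list(n_particles = as.integer(n_particles), seed = seed,
                 resample = resample, ess_fraction = ess_fraction),
            class = "pf_config")
}

#' Fit the second-order state motion model from a training trajectory
#'
#' Regresses `C_{t+1}` on `[C_t, C_{t-1}]` by least squares; the companion
#' form embeds the second-order dependence in a first-order recursion over
#' the augmented state. The process-noise covariance is the sample
#' covariance of the regression residuals (zero on the shift block).
#'
#' @param kin Kinematics tibble (`time` + coordinates) or numeric matrix
#'   with one column per coordinate, at least 4 samples.
#' @return List of class `state_model` with `A` (`2d x 2d`), `Q`
#'   (`2d x 2d`, PSD, nonzero only on the position block), and `d`.
#' @export
fit_state_model <- function(kin) {
  P <- if (is.data.frame(kin)) as_channel_matrix(kin) else as.matrix(kin)
  T_ <- nrow(P)
  d <- ncol(P)
  if (T_ < 4) abort("need at least 4 samples to fit the motion model")
  Y <- P[3:T_, , drop = FALSE]
  X <- cbind(P[2:(T_ - 1), , drop = FALSE], P[1:(T_ - 2), , drop = FALSE])
  B <- lstsq_min_norm(X, Y) # 2d x d
  A <- matrix(0, 2 * d, 2 * d)
  A[seq_len(d), ] <- t(B)
  A[(d + 1):(2 * d), seq_len(d)] <- diag(d)
  res <- Y - X %*% B
  Q <- matrix(0, 2 * d, 2 * d)
  Qtop <- crossprod(res) / (nrow(res) - 1)
  Q[seq_len(d), seq_len(d)] <- (Qtop + t(Qtop)) / 2
  structure(list(A = A, Q = Q, d = d), class = "state_model")
}

#' Fit the Gaussian measurement model from one synchronized trial
#'
#' Each channel's mean is an affine function of the position, fitted by
#' per-channel OLS; the channel noise variance is the residual variance,
#' floored at 1e-8 of the channel variance so the likelihood stays proper.
#' Off-diagonal covariance is zero (conditional independence of channels).
#'
#' @param eeg Tibble `time` + channels.
#' @param kin Tibble `time` + coordinates, same length.
#' @return List of class `measurement_model` with `H` (`m x (d+1)`; last
#'   column is the intercept), `sigma2` (length-m residual variances),
#'   `m`, `d`, and `channel_labels`.
#' @export
fit_measurement_model <- function(eeg, kin) {
  if (nrow(eeg) != nrow(kin)) abort("EEG and kinematics lengths differ")
  S <- as_channel_matrix(eeg)
  P <- as_channel_matrix(kin)
  d <- ncol(P)
  m <- ncol(S)
  vars <- apply(S, 2, var)
  if (any(vars == 0)) {
    abort(paste0("zero-variance channel(s): ",
                 paste(colnames(S)[vars == 0], collapse = ", ")))
  }
  X <- cbind(P, 1)
  B <- lstsq_min_norm(X, S) # (d+1) x m
  res <- S - X %*% B
  dof <- max(nrow(S) - (d + 1), 1)
  sigma2 <- pmax(colSums(res^2) / dof, 1e-8 * vars)
  structure(
    list(H = t(B), sigma2 = as.numeric(sigma2), m = m, d = d,
         channel_labels = colnames(S)),
    class = "measurement_model"
  )
}

#' Gaussian observation log-likelihood of one EEG sample
#'
#' Exact log of the diagonal-Gaussian likelihood with mean
#' `mu = H [position; 1]`, computed in the log domain.
#'
#' @param meas A `measurement_model`.
#' @param s_t Observed m-vector (one EEG sample across channels).
#' @param position d-vector hand position.
#' @return Scalar log-density.
#' @export
log_likelihood <- function(meas, s_t, position) {
  if (!all(is.finite(s_t)) || !all(is.finite(position))) {
    abort("non-finite observation or position")
  }
  if (length(s_t) != meas$m || length(position) != meas$d) {
    abort("dimension mismatch with the measurement model")
  }
  mu <- as.numeric(meas$H %*% c(position, 1))
  -meas$m / 2 * log(2 * pi) - 0.5 * sum(log(meas$sigma2)) -
    0.5 * sum((s_t - mu)^2 / meas$sigma2)
}

# log-likelihood of one observation for every particle (vectorized)
loglik_particles <- function(meas, s_t, positions) {
  Hp <- meas$H[, seq_len(meas$d), drop = FALSE]
  h0 <- meas$H[, meas$d + 1]
  mu <- positions %*% t(Hp) # N x m
  resid2 <- sweep(mu, 2, s_t - h0)^2
  const <- -meas$m / 2 * log(2 * pi) - 0.5 * sum(log(meas$sigma2))
  const - 0.5 * as.numeric(resid2 %*% (1 / meas$sigma2))
}

new_swarm <- function(particles, weights, step = 0L) {
  structure(list(particles = particles, weights = weights, step = step),
            class = "particle_swarm")
}

positions_of <- function(swarm, d) swarm$particles[, seq_len(d), drop = FALSE]

#' Initialize the particle swarm from the training prior
#'
#' Particles are drawn from a Gaussian with the training kinematics' mean
#' and covariance (the lagged half of the augmented state is set equal to
#' the position half); every weight starts at `1 / N_s`.
#'
#' @param state A `state_model`.
#' @param train_kin Training kinematics tibble or matrix.
#' @param config A [pf_config()]; its seed is applied before sampling.
#' @return A `particle_swarm`.
#' @export
pf_init <- function(state, train_kin, config = pf_config()) {
  P <- if (is.data.frame(train_kin)) as_channel_matrix(train_kin) else as.matrix(train_kin)
  d <- state$d
  if (ncol(P) != d) abort("training kinematics dimension differs from the state model")
  if (!is.null(config$seed)) set.seed(derive_seed(config$seed, "pf-init"))
  N <- config$n_particles
  mu0 <- colMeans(P)
  S0 <- stats::cov(P)
  Z <- matrix(rnorm(N * d), N, d)
  pos <- sweep(Z %*% psd_sqrt(S0), 2, mu0, "+")
  new_swarm(cbind(pos, pos), rep(1 / N, N))
}

#' Update particle weights with one EEG observation
#'
#' Multiplies each weight by the observation likelihood of the particle's
#' position and renormalizes. Computed via log-weights with
#' max-subtraction, so extreme likelihood ratios cannot underflow.
#'
#' @param swarm A `particle_swarm` with normalized weights.
#' @param meas A `measurement_model`.
#' @param s_t Observed m-vector.
#' @return The reweighted swarm (weights sum to 1).
#' @export
pf_update <- function(swarm, meas, s_t) {
  ll <- loglik_particles(meas, s_t, positions_of(swarm, meas$d))
  logw <- log(swarm$weights) + ll
  mx <- max(logw)
  if (!is.finite(mx)) {
    abort("measurement model collapse: all particle log-likelihoods are -Inf")
  }
  w <- exp(logw - mx)
  swarm$weights <- w / sum(w)
  swarm$step <- swarm$step + 1L
  swarm
}

#' Posterior-mean position estimate from the swarm
#'
#' The least mean-square estimate `sum_i w_i c_i` over the position block.
#'
#' @param swarm A `particle_swarm` with normalized weights.
#' @param d State dimension; defaults to half the augmented state width.
#' @return d-vector.
#' @export
pf_estimate <- function(swarm, d = ncol(swarm$particles) %/% 2) {
  as.numeric(crossprod(positions_of(swarm, d), swarm$weights))
}

#' Systematic resampling of the swarm
#'
#' Draws one uniform offset and takes `N_s` evenly spaced points through
#' the cumulative weights, so the expected offspring count of particle i
#' is exactly `N_s * w_i` and uniform weights copy every particle once.
#' Output weights are all `1 / N_s`.
#'
#' @param swarm A `particle_swarm` with normalized weights.
#' @return The resampled swarm.
#' @export
pf_resample <- function(swarm) {
  N <- length(swarm$weights)
  cw <- cumsum(swarm$weights)
  cw <- cw / cw[N] # guard the last step against 1-ulp overshoot
  pts <- (runif(1) + 0:(N - 1)) / N
  idx <- findInterval(pts, cw, left.open = TRUE) + 1L
  new_swarm(swarm$particles[idx, , drop = FALSE], rep(1 / N, N), swarm$step)
}

#' Propagate the swarm one step through the motion model
#'
#' Applies the state recursion to every particle and adds independent
#' Gaussian process noise `N(0, Q)`; weights are untouched.
#'
#' @param swarm A `particle_swarm`.
#' @param state A `state_model`.
#' @return The propagated swarm.
#' @export
pf_predict <- function(swarm, state) {
  X <- swarm$particles %*% t(state$A)
  d <- state$d
  Qtop <- state$Q[seq_len(d), seq_len(d), drop = FALSE]
  if (any(Qtop != 0)) {
    Z <- matrix(rnorm(nrow(X) * d), ncol = d)
    X[, seq_len(d)] <- X[, seq_len(d)] + Z %*% psd_sqrt(Qtop)
  }
  swarm$particles <- X
  swarm
}

#' Decode a trajectory from EEG with the particle filter
#'
#' Runs init, then for each EEG sample: weight update, posterior-mean
#' estimate, resampling (per the configured schedule), and prediction.
#' Deterministic given `config$seed`.
#'
#' @param eeg Tibble `time` + channels matching the measurement model.
#' @param state A `state_model`.
#' @param meas A `measurement_model`.
#' @param config A [pf_config()].
#' @param train_kin Training kinematics used for the initial prior
#'   (defaults to a standard-normal prior if omitted).
#' @param train_norm Optional list with `mean` and `sd` (length d) used to
#'   de-standardize the decoded positions.
#' @return Kinematics tibble (`time` + coordinates) of posterior means.
#' @export
pf_decode <- function(eeg, state, meas, config = pf_config(),
                      train_kin = NULL, train_norm = NULL) {
  labels <- channel_names(eeg)
  if (length(labels) != meas$m) {
    if (all(meas$channel_labels %in% labels)) {
      eeg <- eeg[c("time", meas$channel_labels)]
    } else {
      abort("EEG channel count does not match the measurement model")
    }
  }
  S <- as_channel_matrix(eeg)
  d <- state$d
  if (is.null(train_kin)) {
    train_kin <- matrix(rnorm(200 * d), ncol = d)
  }
  swarm <- pf_init(state, train_kin, config)
  set.seed(derive_seed(config$seed, "pf-decode"))
  T_ <- nrow(S)
  est <- matrix(NA_real_, T_, d)
  for (t in seq_len(T_)) {
    swarm <- pf_update(swarm, meas, S[t, ])
    est[t, ] <- pf_estimate(swarm, d)
    do_resample <- config$resample == "every_step" ||
      1 / sum(swarm$weights^2) < config$ess_fraction * length(swarm$weights)
    if (do_resample) swarm <- pf_resample(swarm)
    swarm <- pf_predict(swarm, state)
  }
  if (!is.null(train_norm)) {
    est <- sweep(sweep(est, 2, train_norm$sd, "*"), 2, train_norm$mean, "+")
  }
  new_kin(eeg$time, est)
}

#' Fit the full particle-filter model from one training trial
#'
#' Convenience wrapper bundling [fit_state_model()],
#' [fit_measurement_model()], and the training normalization statistics.
#'
#' @param eeg,kin Synchronized training EEG and kinematics tibbles.
#' @return List of class `pf_model` with `state`, `meas`, `train_kin`, and
#'   `train_norm`.
#' @export
fit_pf <- function(eeg, kin) {
  P <- as_channel_matrix(kin)
  structure(
    list(state = fit_state_model(kin),
         meas = fit_measurement_model(eeg, kin),
         train_kin = P,
         train_norm = list(mean = colMeans(P), sd = apply(P, 2, sd)),
         coord_labels = channel_names(kin)),
    class = "pf_model"
  )
}

#' @export
predict.pf_model <- function(object, newdata, config = pf_config(),
                             destandardize = FALSE, ...) {
  out <- pf_decode(newdata, object$state, object$meas, config,
                   train_kin = object$train_kin,
                   train_norm = if (destandardize) object$train_norm)
  names(out) <- c("time", object$coord_labels)
  out
}

#' @export
print.pf_model <- function(x, ...) {
  cat(sprintf(
    "<pf_model> %dD second-order motion prior + %d-channel Gaussian likelihood\n",
    x$state$d, x$meas$m))
  invisible(x)
}
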