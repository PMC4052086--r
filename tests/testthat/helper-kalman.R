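# Independent Kalman filter oracle for linear-Gaussian systems, used to
# check the particle filter's posterior mean. Kept deliberately separate
# from the package implementation: plain textbook predict/update recursion.

kalman_filter <- function(S, A, Q, C, d0, Rdiag, x0, P0) {
  T_ <- nrow(S)
  n <- length(x0)
  x <- matrix(x0, ncol = 1)
  P <- P0
  out <- matrix(0, T_, n)
  for (t in seq_len(T_)) {
    innov <- S[t, ] - d0 - C %*% x
    Sm <- C %*% P %*% t(C) + diag(Rdiag, length(Rdiag))
    K <- P %*% t(C) %*% solve(Sm)
    x <- x + K %*% innov
    P <- P - K %*% C %*% P
    out[t, ] <- x
    x <- A %*% x
    P <- A %*% P %*% t(A) + Q
  }
  out
}

# simulate a d-dimensional second-order linear-Gaussian system in
# companion form with an affine Gaussian observation model
simulate_lgss <- function(T_ = 500, d = 2, m = 10, q = 0.02, seed = 1,
                          rho = 1.6, rho2 = -0.64) {
  set.seed(seed)
  A <- rbind(cbind(diag(d) * rho, diag(d) * rho2),
             cbind(diag(d), matrix(0, d, d)))
  Q <- matrix(0, 2 * d, 2 * d)
  Q[seq_len(d), seq_len(d)] <- diag(d) * q
  H <- cbind(matrix(rnorm(m * d), m, d), rnorm(m))
  sig2 <- runif(m, 0.5, 2)
  x <- rnorm(2 * d)
  X <- matrix(0, T_, 2 * d)
  S <- matrix(0, T_, m)
  for (t in seq_len(T_)) {
    x <- A %*% x
    x[seq_len(d)] <- x[seq_len(d)] + rnorm(d, 0, sqrt(q))
    X[t, ] <- x
    S[t, ] <- H %*% c(x[seq_len(d)], 1) + rnorm(m, 0, sqrt(sig2))
  }
  list(A = A, Q = Q, H = H, sig2 = sig2, X = X, S = S, d = d, m = m)
}

lgss_models <- function(sim) {
  list(
    state = structure(list(A = sim$A, Q = sim$Q, d = sim$d),
                      class = "state_model"),
    meas = structure(list(H = sim$H, sigma2 = sim$sig2, m = sim$m,
                          d = sim$d,
                          channel_labels = paste0("CH", seq_len(sim$m))),
                     class = "measurement_model")
  )
}

# The oracle starts from the same prior the particle swarm is initialized
# with: position mean/covariance from the training positions, with the
# lagged half of the augmented state a copy of the position half.
run_kalman_oracle <- function(sim) {
  d <- sim$d
  C <- cbind(sim$H[, seq_len(d), drop = FALSE], matrix(0, sim$m, d))
  mu0 <- colMeans(sim$X[, seq_len(d), drop = FALSE])
  S0 <- stats::cov(sim$X[, seq_len(d), drop = FALSE])
  P0 <- rbind(cbind(S0, S0), cbind(S0, S0))
  kalman_filter(sim$S, sim$A, sim$Q, C, sim$H[, d + 1], sim$sig2,
                x0 = c(mu0, mu0), P0 = P0)
}
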