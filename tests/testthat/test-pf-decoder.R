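# Particle filter: model fitting, likelihood arithmetic, swarm mechanics,
# and agreement with the Kalman oracle on linear-Gaussian systems.

test_that("state model recovers a deterministic second-order recursion", {
  c_ <- numeric(200)
  c_[1:2] <- c(0.3, 0.5)
  for (t in 3:200) c_[t] <- 0.9 * c_[t - 1] + 0.05 * c_[t - 2]
  sm <- fit_state_model(matrix(c_, ncol = 1))
  expect_equal(sm$A[1, ], c(0.9, 0.05), tolerance = 1e-8)
  expect_equal(sm$A[2, ], c(1, 0))
  expect_lt(max(abs(sm$Q)), 1e-12)
  expect_error(fit_state_model(matrix(1:3, ncol = 1)), "at least 4")
})

test_that("state model on a constant trajectory is a unit recursion with no noise", {
  sm <- fit_state_model(make_kin2d(rep(1, 50) + 1e-9 * sin(1:50),
                                   rep(2, 50) + 1e-9 * cos(1:50)))
  pos <- sm$A[1:2, 1:2] %*% c(1, 2) + sm$A[1:2, 3:4] %*% c(1, 2)
  expect_equal(as.numeric(pos), c(1, 2), tolerance = 1e-4)
  expect_lt(max(abs(sm$Q)), 1e-12)
})

test_that("process-noise covariance is consistent on white noise", {
  set.seed(10)
  P <- matrix(rnorm(10000, sd = 0.7), ncol = 1)
  sm <- fit_state_model(P)
  expect_equal(sm$Q[1, 1], 0.49, tolerance = 0.05)
})

test_that("measurement model is exact per-channel OLS with floored variance", {
  set.seed(11)
  kin <- make_kin2d(rnorm(500), rnorm(500), rate = 64)
  eeg <- make_eeg(list(2 * kin$x + 1, rnorm(500)), rate = 64)
  mm <- fit_measurement_model(eeg, kin)
  expect_identical(nrow(mm$H), 2L)
  expect_equal(mm$H[1, ], c(2, 0, 1), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(mm$sigma2[1], 1e-8 * var(eeg$CH1), tolerance = 1e-6)
  # channel independent of the state: slope ~ 0, variance ~ channel variance
  expect_lt(max(abs(mm$H[2, 1:2])), 0.15)
  expect_equal(mm$sigma2[2], var(eeg$CH2), tolerance = 0.05)
  expect_error(fit_measurement_model(make_eeg(list(rep(1, 500)), rate = 64),
                                     kin), "zero-variance")
})

test_that("log-likelihood matches the closed form", {
  mm <- structure(list(H = matrix(c(1, 0, 0), 1), sigma2 = 1, m = 1L,
                       d = 2L, channel_labels = "CH1"),
                  class = "measurement_model")
  # observation at the mean: only the normalizing constant remains
  expect_equal(log_likelihood(mm, 0.5, c(0.5, 9)), -0.5 * log(2 * pi))
  # unit variance, residual 2
  expect_equal(log_likelihood(mm, 2.5, c(0.5, 0)), -0.5 * log(2 * pi) - 2)
  # doubling the variance: -log(2)/2 and the quadratic term halves
  mm2 <- mm
  mm2$sigma2 <- 2
  expect_equal(log_likelihood(mm2, 2.5, c(0.5, 0)),
               -0.5 * log(2 * pi) - 0.5 * log(2) - 1)
  expect_error(log_likelihood(mm, NaN, c(0, 0)), "non-finite")
})

test_that("initialization matches the training prior with uniform weights", {
  kin <- make_kin2d(rnorm(300, 3, 2), rnorm(300, -1, 0.5))
  sm <- fit_state_model(kin)
  sw <- pf_init(sm, kin, pf_config(n_particles = 20000, seed = 4))
  expect_true(all(sw$weights == 1 / 20000))
  expect_equal(colMeans(sw$particles[, 1:2]), c(mean(kin$x), mean(kin$y)),
               tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(sd(sw$particles[, 1]), sd(kin$x), tolerance = 0.05)
  sw2 <- pf_init(sm, kin, pf_config(n_particles = 20000, seed = 4))
  expect_identical(sw, sw2)
  expect_error(pf_config(n_particles = 1), "n_particles")
})

test_that("weight updates renormalize and concentrate on likely particles", {
  mm <- structure(list(H = matrix(c(1, 0, 0), 1), sigma2 = 1e-4, m = 1L,
                       d = 2L, channel_labels = "CH1"),
                  class = "measurement_model")
  sm <- structure(list(A = diag(4), Q = matrix(0, 4, 4), d = 2L),
                  class = "state_model")
  particles <- cbind(c(0, 5, -5, 7), c(0, 0, 0, 0))
  sw <- structure(list(particles = cbind(particles, particles),
                       weights = rep(0.25, 4), step = 0L),
                  class = "particle_swarm")
  up <- pf_update(sw, mm, 0)
  expect_equal(sum(up$weights), 1, tolerance = 1e-12)
  expect_gt(up$weights[1], 1 - 1e-9)
  # uniform likelihood leaves weights unchanged
  mm_flat <- mm
  mm_flat$H <- matrix(c(0, 0, 0), 1)
  mm_flat$sigma2 <- 1
  up2 <- pf_update(sw, mm_flat, 0)
  expect_equal(up2$weights, sw$weights, tolerance = 1e-12)
})

test_that("posterior-mean estimate equals the direct weighted sum", {
  set.seed(12)
  particles <- matrix(rnorm(400), 100, 4)
  w <- runif(100)
  w <- w / sum(w)
  sw <- structure(list(particles = particles, weights = w, step = 0L),
                  class = "particle_swarm")
  expect_equal(pf_estimate(sw, 2),
               c(sum(w * particles[, 1]), sum(w * particles[, 2])),
               tolerance = 1e-12)
  sw$weights <- c(1, rep(0, 99))
  expect_equal(pf_estimate(sw, 2), particles[1, 1:2], tolerance = 1e-15)
  # two symmetric particles cancel
  sw2 <- structure(list(particles = rbind(rep(1, 4), rep(-1, 4)),
                        weights = c(0.5, 0.5), step = 0L),
                   class = "particle_swarm")
  expect_equal(pf_estimate(sw2, 2), c(0, 0))
})

test_that("systematic resampling keeps uniform swarms and collapses onto sure particles", {
  set.seed(13)
  particles <- matrix(rnorm(40), 10, 4)
  sw <- structure(list(particles = particles, weights = rep(0.1, 10),
                       step = 0L), class = "particle_swarm")
  rs <- pf_resample(sw)
  expect_identical(rs$particles, particles) # uniform: every particle once
  expect_true(all(rs$weights == 0.1))
  sw$weights <- c(rep(0, 6), 1, rep(0, 3))
  rs2 <- pf_resample(sw)
  expect_true(all(rs2$particles[, 1] == particles[7, 1]))
})

test_that("prediction propagates exactly and matches the covariance identity", {
  sm0 <- structure(list(A = diag(4), Q = matrix(0, 4, 4), d = 2L),
                   class = "state_model")
  set.seed(14)
  particles <- matrix(rnorm(4000), 1000, 4)
  sw <- structure(list(particles = particles,
                       weights = rep(1e-3, 1000), step = 0L),
                  class = "particle_swarm")
  expect_identical(pf_predict(sw, sm0)$particles, particles)
  sm2 <- sm0
  sm2$A <- diag(4) * 2
  expect_equal(pf_predict(sw, sm2)$particles, particles * 2)
  smq <- sm0
  smq$Q[1:2, 1:2] <- diag(2) * 0.25
  prop <- pf_predict(sw, smq)$particles
  expect_equal(stats::cov(prop[, 1:2]), stats::cov(particles[, 1:2]) + diag(2) * 0.25,
               tolerance = 0.05)
})

test_that("particle filter tracks the Kalman posterior mean on a linear-Gaussian system", {
  sim <- simulate_lgss(T_ = 300, d = 2, m = 8, seed = 20)
  models <- lgss_models(sim)
  eeg <- make_eeg(asplit(sim$S, 2), rate = 64)
  names(eeg) <- c("time", paste0("CH", 1:8))
  dec <- pf_decode(eeg, models$state, models$meas,
                   pf_config(n_particles = 5000, seed = 6),
                   train_kin = sim$X[, 1:2])
  km <- run_kalman_oracle(sim)
  # first 5 steps are burn-in (importance weights can collapse before the
  # first resampling cycles flush the prior), as in decoder scoring
  err <- (as.matrix(dec[, c("x", "y")]) - km[, 1:2])^2
  rmse <- sqrt(mean(err[-(1:5), ]))
  expect_lt(rmse, 0.05 * sd(sim$X[, 1:2]))
  dec2 <- pf_decode(eeg, models$state, models$meas,
                    pf_config(n_particles = 5000, seed = 6),
                    train_kin = sim$X[, 1:2])
  expect_identical(dec, dec2)
})

test_that("weights stay normalized and finite through a full decode", {
  sim <- simulate_lgss(T_ = 80, d = 2, m = 4, seed = 21)
  models <- lgss_models(sim)
  sw <- pf_init(models$state, sim$X[, 1:2],
                pf_config(n_particles = 200, seed = 2))
  set.seed(99)
  for (t in seq_len(nrow(sim$S))) {
    sw <- pf_update(sw, models$meas, sim$S[t, ])
    expect_equal(sum(sw$weights), 1, tolerance = 1e-12)
    expect_true(all(is.finite(sw$particles)))
    sw <- pf_resample(sw)
    sw <- pf_predict(sw, models$state)
  }
})

test_that("ESS-triggered resampling mode decodes comparably", {
  sim <- simulate_lgss(T_ = 150, d = 2, m = 6, seed = 22)
  models <- lgss_models(sim)
  eeg <- make_eeg(asplit(sim$S, 2), rate = 64)
  names(eeg) <- c("time", paste0("CH", 1:6))
  dec <- pf_decode(eeg, models$state, models$meas,
                   pf_config(n_particles = 1000, seed = 3,
                             resample = "ess_threshold"),
                   train_kin = sim$X[, 1:2])
  expect_gt(pearson_r(dec$x, sim$X[, 1]), 0.8)
})

test_that("fit_pf bundles the models and round-trips predictions", {
  set.seed(23)
  kin <- generate_trajectory("spiral2d", 10, 64, seed = 5)
  eeg <- make_eeg(list(kin$x * 2 + rnorm(640, sd = 0.1),
                       kin$y - kin$x + rnorm(640, sd = 0.1),
                       rnorm(640)), rate = 64)
  m <- fit_pf(eeg, kin)
  expect_s3_class(m, "pf_model")
  pred <- predict(m, eeg, config = pf_config(n_particles = 500, seed = 9))
  expect_gt(pearson_r(pred$x, kin$x), 0.9)
  td <- tidy(m)
  expect_identical(nrow(td), 3L)
  expect_equal(td$slope_x[1], 2, tolerance = 0.05)
  expect_identical(names(glance(m)),
                   c("d", "m_channels", "spectral_radius",
                     "process_noise_tr", "mean_meas_noise"))
})
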