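# Lagged multiple linear regression decoder: each coordinate of the hand
# position at time t is a linear combination of the voltages of all
# channels at lags 0..L plus an intercept,
#   x(t) = a_x + sum_n sum_k b_nk^x S_n(t - k),
# with the weights fitted by least squares (minimum-norm on rank-deficient
# designs). Multi-trial training concatenates per-trial design matrices so
# lag windows never straddle trial boundaries.

#' Build the lagged design matrix for the linear decoder
#'
#' Rows are the usable time points `t = L+1 .. T` (1-based); columns are an
#' intercept followed by channel-major blocks of lags `k = 0..L`, i.e.
#' channel 1 at lags 0..L, then channel 2, and so on.
#'
#' @param eeg Tibble `time` + channels.
#' @param L Number of time lags.
#' @return List with `X` (`(T-L) x (1 + N(L+1))` matrix) and `row_index`
#'   (the original sample index of each row).
#' @export
build_design_matrix <- function(eeg, L) {
  S <- as_channel_matrix(eeg)
  T_ <- nrow(S)
  N <- ncol(S)
  if (L >= T_) abort("number of lags must be smaller than the sample count")
  E <- stats::embed(S, L + 1) # lag-major blocks: [S_t, S_{t-1}, ...]
  # reorder to channel-major: channel n at lags 0..L contiguous
  perm <- as.vector(vapply(seq_len(N), function(n) n + N * (0:L),
                           numeric(L + 1)))
  X <- cbind(1, E[, perm, drop = FALSE])
  lag_lab <- as.vector(vapply(colnames(S), function(ch)
    paste0(ch, ".lag", 0:L), character(L + 1)))
  colnames(X) <- c("(intercept)", lag_lab)
  list(X = X, row_index = (L + 1):T_)
}

train_norm_stats <- function(M) {
  mu <- colMeans(M)
  sdv <- apply(M, 2, sd)
  sdv[sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

#' Fit the lagged linear decoder
#'
#' Per-coordinate least squares of the (standardized) positions on the
#' lagged (standardized) EEG; weights and intercepts are mapped back to the
#' original units, so predictions come out de-standardized. For multiple
#' training trials pass lists of EEG and kinematics tibbles: design
#' matrices are built per trial and stacked without lag windows crossing
#' trial boundaries.
#'
#' The solver is plain minimum-norm least squares (SVD pseudo-inverse at
#' the machine-precision numerical rank): the model itself carries no
#' regularization. The default lag window is short because at a 64 Hz
#' decoding rate the channels are band-limited to 2 Hz, so adjacent lags
#' are nearly collinear and windows much longer than ~50 ms add no
#' information while inflating the condition number of the design.
#' `sv_tol` sets a larger relative singular-value cutoff when a more
#' aggressive numerical-rank decision is wanted.
#'
#' @param eeg Tibble `time` + channels, or a list of them.
#' @param kin Tibble `time` + coordinates (same length/rate as its EEG), or
#'   a list matching `eeg`.
#' @param L Number of time lags (default 2; about 47 ms at 64 Hz).
#' @param sv_tol Relative singular-value cutoff for the pseudo-inverse;
#'   `NULL` (default) uses the machine-precision numerical rank.
#' @return An object of class `mlr_decoder` with `intercepts` (d-vector),
#'   `weights` (`N x (L+1) x d` array), `n_lags`, `channel_labels`,
#'   `train_norm`, and the numerical `rank` used.
#' @export
fit_mlr <- function(eeg, kin, L = 2, sv_tol = NULL) {
  if (!is.list(eeg) || is.data.frame(eeg)) {
    eeg <- list(eeg)
    kin <- list(kin)
  }
  if (length(eeg) != length(kin)) abort("eeg and kin trial lists differ in length")
  labels <- channel_names(eeg[[1]])
  d <- length(channel_names(kin[[1]]))
  for (i in seq_along(eeg)) {
    if (nrow(eeg[[i]]) != nrow(kin[[i]])) {
      abort(sprintf("trial %d: EEG and kinematics lengths differ (%d vs %d); synchronize first",
                    i, nrow(eeg[[i]]), nrow(kin[[i]])))
    }
    if (!identical(channel_names(eeg[[i]]), labels)) {
      abort("all training trials must share the same channel labels")
    }
  }
  Sall <- do.call(rbind, lapply(eeg, as_channel_matrix))
  Pall <- do.call(rbind, lapply(kin, as_channel_matrix))
  snorm <- train_norm_stats(Sall)
  pnorm <- train_norm_stats(Pall)

  parts <- lapply(seq_along(eeg), function(i) {
    ez <- eeg[[i]]
    for (j in seq_along(labels)) {
      ez[[labels[j]]] <- (ez[[labels[j]]] - snorm$mean[j]) / snorm$sd[j]
    }
    dm <- build_design_matrix(ez, L)
    Pz <- sweep(sweep(as_channel_matrix(kin[[i]]), 2, pnorm$mean), 2,
                pnorm$sd, "/")
    list(X = dm$X, Y = Pz[dm$row_index, , drop = FALSE])
  })
  X <- do.call(rbind, lapply(parts, `[[`, "X"))
  Y <- do.call(rbind, lapply(parts, `[[`, "Y"))
  sv <- svd(X)
  tol <- if (is.null(sv_tol)) max(dim(X)) * .Machine$double.eps else sv_tol
  rank <- sum(sv$d > tol * sv$d[1])
  B <- sv$v[, seq_len(rank), drop = FALSE] %*%
    (crossprod(sv$u[, seq_len(rank), drop = FALSE], Y) / sv$d[seq_len(rank)])

  N <- length(labels)
  a_std <- B[1, ]
  W_std <- array(t(B[-1, , drop = FALSE]), dim = c(d, L + 1, N))
  W_std <- aperm(W_std, c(3, 2, 1)) # N x (L+1) x d

  # back-transform to original units:
  # b_raw = sd_pos * b_std / sd_chan; a_raw folds the channel means back in
  weights <- W_std
  for (j in seq_len(d)) {
    Wj <- matrix(W_std[, , j], nrow = N)
    weights[, , j] <- pnorm$sd[j] * Wj / snorm$sd # recycles per channel row
  }
  intercepts <- vapply(seq_len(d), function(j) {
    pnorm$mean[j] + pnorm$sd[j] *
      (a_std[j] - sum(W_std[, , j] * (snorm$mean / snorm$sd)))
  }, numeric(1))

  fitted_std <- X %*% B
  r_train <- vapply(seq_len(d), function(j) {
    if (sd(Y[, j]) == 0 || sd(fitted_std[, j]) == 0) NA_real_
    else cor(Y[, j], fitted_std[, j])
  }, numeric(1))

  structure(
    list(intercepts = intercepts, weights = weights, n_lags = L,
         channel_labels = labels,
         coord_labels = channel_names(kin[[1]]),
         train_norm = list(channels = snorm, coords = pnorm),
         rank = rank, r_train = r_train, n_train_samples = nrow(X)),
    class = "mlr_decoder"
  )
}

#' Predict hand positions with a fitted linear decoder
#'
#' Channels are aligned to the model by label, so column order in the input
#' is irrelevant. The first `L` samples have no complete lag window and are
#' returned as `NA` (excluded from scoring).
#'
#' @param model An `mlr_decoder`.
#' @param eeg Tibble `time` + channels covering at least the model's
#'   channel labels.
#' @return Kinematics tibble (`time` + coordinates) with `NA` in the first
#'   `L` rows.
#' @export
predict_mlr <- function(model, eeg) {
  missing <- setdiff(model$channel_labels, channel_names(eeg))
  if (length(missing) > 0) {
    abort(paste0("EEG is missing model channels: ",
                 paste(missing, collapse = ", ")))
  }
  eeg <- eeg[c("time", model$channel_labels)]
  dm <- build_design_matrix(eeg, model$n_lags)
  d <- length(model$intercepts)
  N <- length(model$channel_labels)
  L <- model$n_lags
  Bmat <- vapply(seq_len(d), function(j) as.vector(t(model$weights[, , j])),
                 numeric(N * (L + 1)))
  pred <- sweep(dm$X[, -1, drop = FALSE] %*% Bmat, 2, model$intercepts, "+")
  out <- matrix(NA_real_, nrow(eeg), d)
  out[dm$row_index, ] <- pred
  res <- new_kin(eeg$time, out)
  names(res) <- c("time", model$coord_labels)
  res
}

#' @export
predict.mlr_decoder <- function(object, newdata, ...) predict_mlr(object, newdata)

#' @export
print.mlr_decoder <- function(x, ...) {
  cat(sprintf(
    "<mlr_decoder> %d channels x %d lags -> %dD position; training r: %s\n",
    length(x$channel_labels), x$n_lags + 1, length(x$intercepts),
    paste(sprintf("%.3f", x$r_train), collapse = ", ")))
  invisible(x)
}

#' Per-channel weight magnitude of a linear decoder
#'
#' The contribution of each electrode summarized as the maximum absolute
#' weight across lags and coordinates ("at the best lag"), the convention
#' used for topographic contribution maps.
#'
#' @param model An `mlr_decoder`.
#' @return Tibble with `channel` and `weight` columns.
#' @export
mlr_weight_map <- function(model) {
  w <- apply(abs(model$weights), 1, max)
  tibble::tibble(channel = model$channel_labels, weight = w)
}
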