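# Internal helpers shared across modules: seed derivation, minimum-norm
# least squares, channel bookkeeping, and rate inference from timestamps.

MOD31 <- 2147483647 # 2^31 - 1; all derived seeds stay below this

#' Derive a child RNG seed from a master seed and a purpose label
#'
#' Stable string hashing keeps independent stages on independent streams:
#' adding a new stage never perturbs the random numbers another stage draws.
#'
#' @param master Integer master seed.
#' @param purpose Character label naming the consumer of the stream.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "trial1")
derive_seed <- function(master, purpose) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(purpose))
  h <- 0
  for (code in utf8ToInt(purpose)) h <- (h * 31 + code) %% MOD31
  as.integer((h + (abs(master) %% MOD31) * 48271) %% (MOD31 - 1) + 1)
}

# Minimum-norm least squares via SVD: returns the pseudo-inverse solution,
# well-defined for rank-deficient designs (near-collinear EEG channels are
# routine, so erroring out is not an option).
lstsq_min_norm <- function(X, Y, tol = NULL) {
  Y <- as.matrix(Y)
  sv <- svd(X)
  tol <- tol %||% (max(dim(X)) * .Machine$double.eps * sv$d[1])
  keep <- sv$d > tol
  if (!any(keep)) return(matrix(0, ncol(X), ncol(Y)))
  crossprod(
    t(sv$v[, keep, drop = FALSE]),
    (crossprod(sv$u[, keep, drop = FALSE], Y)) / sv$d[keep]
  )
}

# Channel columns of an EEG/kinematics tibble (everything except time)
channel_names <- function(df) setdiff(names(df), "time")

as_channel_matrix <- function(df) {
  as.matrix(df[channel_names(df)])
}

#' Infer the sampling rate of a timestamped recording
#'
#' @param df Tibble with a `time` column in seconds.
#' @param max_jitter Maximum tolerated relative deviation of timestamp
#'   increments from their median before the series is declared irregular.
#' @return Sampling rate in Hz.
#' @export
signal_rate <- function(df, max_jitter = 0.01) {
  tt <- df[["time"]]
  if (is.null(tt)) abort("data must have a `time` column (seconds)")
  if (length(tt) < 2) abort("need at least two samples to infer a rate")
  dt <- diff(tt)
  if (any(dt <= 0)) {
    abort(sprintf("timestamps not strictly increasing at line %d",
                  which(dt <= 0)[1] + 1L))
  }
  med <- median(dt)
  if (any(abs(dt - med) > max_jitter * med)) {
    abort(sprintf(
      "irregular timestamps (jitter > %.1f%% of the median interval) at line %d",
      100 * max_jitter, which(abs(dt - med) > max_jitter * med)[1] + 1L))
  }
  1 / med
}

check_finite <- function(x, what) {
  if (!all(is.finite(as.matrix(x)))) abort(paste0("non-finite values in ", what))
  invisible(x)
}

#' Channel labels of the extended 10-20 montage
#'
#' The 30-channel montage of a standard EEG cap, ordered frontal to
#' occipital. The first `n` labels name the channels of n-channel
#' synthetic recordings, so FP1/FP2 are present and can be dropped as in
#' real pipelines.
#'
#' @param n Number of labels to return.
#' @return Character vector of channel labels.
#' @export
#' @examples
#' montage_10_20(5)
montage_10_20 <- function(n = 30) {
  labels <- c(
    "FP1", "FP2", "F7", "F3", "FZ", "F4", "F8",
    "FT7", "FC3", "FCZ", "FC4", "FT8",
    "T3", "C3", "CZ", "C4", "T4",
    "TP7", "CP3", "CPZ", "CP4", "TP8",
    "T5", "P3", "PZ", "P4", "T6",
    "O1", "OZ", "O2"
  )
  if (n > length(labels)) {
    labels <- c(labels, sprintf("CH%02d", seq_len(n - length(labels))))
  }
  labels[seq_len(n)]
}

# Matrix square root of a symmetric PSD matrix (eigen-based; chol fails on
# the singular process-noise covariance of the companion-form state).
psd_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

new_eeg <- function(time, data, labels = colnames(data)) {
  out <- tibble::as_tibble(as.data.frame(data))
  names(out) <- labels
  dplyr::bind_cols(tibble::tibble(time = time), out)
}

new_kin <- function(time, positions) {
  d <- ncol(positions)
  stopifnot(d %in% 1:3)
  out <- tibble::as_tibble(as.data.frame(positions))
  names(out) <- c("x", "y", "z")[seq_len(d)]
  dplyr::bind_cols(tibble::tibble(time = time), out)
}
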