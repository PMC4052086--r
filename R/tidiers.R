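# broom-style tidiers for the fitted decoders.

#' Tidy a fitted linear decoder
#'
#' One row per channel x lag x coordinate weight.
#'
#' @param x An `mlr_decoder`.
#' @param ... Unused.
#' @return Tibble with `channel`, `lag`, `dim`, `estimate`.
#' @export
tidy.mlr_decoder <- function(x, ...) {
  d <- length(x$intercepts)
  L <- x$n_lags
  tidyr::expand_grid(
    channel = x$channel_labels,
    lag = 0:L,
    dim = x$coord_labels
  ) |>
    dplyr::mutate(estimate = as.numeric(aperm(x$weights, c(3, 2, 1))))
}

#' @rdname tidy.mlr_decoder
#' @export
glance.mlr_decoder <- function(x, ...) {
  tibble::tibble(
    n_channels = length(x$channel_labels),
    n_lags = x$n_lags,
    n_coords = length(x$intercepts),
    n_train_samples = x$n_train_samples,
    r_train = mean(x$r_train)
  )
}

#' Tidy a fitted particle-filter model
#'
#' One row per channel of the measurement model: position slopes,
#' intercept, and noise variance.
#'
#' @param x A `pf_model`.
#' @param ... Unused.
#' @return Tibble with `channel`, one slope column per coordinate,
#'   `intercept`, `sigma2`.
#' @export
tidy.pf_model <- function(x, ...) {
  H <- x$meas$H
  d <- x$meas$d
  slopes <- tibble::as_tibble(as.data.frame(H[, seq_len(d), drop = FALSE]))
  names(slopes) <- paste0("slope_", x$coord_labels)
  dplyr::bind_cols(
    tibble::tibble(channel = x$meas$channel_labels),
    slopes,
    tibble::tibble(intercept = H[, d + 1], sigma2 = x$meas$sigma2)
  )
}

#' @rdname tidy.pf_model
#' @export
glance.pf_model <- function(x, ...) {
  d <- x$state$d
  tibble::tibble(
    d = d,
    m_channels = x$meas$m,
    spectral_radius = max(Mod(eigen(x$state$A, only.values = TRUE)$values)),
    process_noise_tr = sum(diag(x$state$Q)[seq_len(d)]),
    mean_meas_noise = mean(x$meas$sigma2)
  )
}
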