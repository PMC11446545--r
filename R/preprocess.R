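#' Default extension factor
#'
#' The extension factor is `round(1000 / m)` with a floor of 1, where `m` is
#' the number of retained channels (about 16 delayed repetitions for a
#' 64-channel grid, 63 for a 16-electrode array).
#'
#' @param m number of channels.
#' @return integer extension factor.
#' @export
default_extension_factor <- function(m, target = 1000) max(1L, as.integer(round(target / m)))

# low-level: stack each row of x with R - 1 delayed copies (zero-padded at the
# start). Row (i - 1) * R + r is channel i delayed by r - 1 samples.
extend_matrix <- function(x, R) {
  m <- nrow(x); T_len <- ncol(x)
  E <- matrix(0, m * R, T_len)
  for (i in seq_len(m)) {
    for (r in seq_len(R)) {
      row <- (i - 1L) * R + r
      if (r == 1L) E[row, ] <- x[i, ]
      else E[row, r:T_len] <- x[i, seq_len(T_len - r + 1L)]
    }
  }
  E
}

#' Extend a recording
#'
#' Turns the convolutive mixture into an (approximately) instantaneous one by
#' stacking each channel with `R - 1` delayed copies of itself, zero-padded at
#' the start.
#'
#' @param rec an [new_emg_recording()] (already masked).
#' @param R extension factor; default [default_extension_factor()] of the
#'   channel count.
#' @return An `ext_signal`: `extended` (`m * R` x samples), `R`, channel
#'   count `m`, `sampling_rate`.
#' @export
extend_emg <- function(rec, R = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  R <- R %||% default_extension_factor(nrow(rec$data))
  if (!is.numeric(R) || R < 1)
    abort("R must be >= 1", class = "mudecomp_invalid_argument")
  R <- as.integer(R)
  structure(list(extended = extend_matrix(rec$data, R), R = R,
                 m = nrow(rec$data), sampling_rate = rec$sampling_rate,
                 mask_applied = rec$meta$mask_applied %||% rep(TRUE, nrow(rec$data))),
            class = "ext_signal")
}

#' Demean and whiten an extended signal
#'
#' Subtracts each extended row's mean, eigendecomposes the extended
#' covariance, discards components whose eigenvalue falls below the
#' regularisation floor (the mean of the smallest half of the spectrum by
#' default) and scales the retained subspace to unit covariance. The
#' whitening matrix and the row means are stored so the identical transform
#' can be re-applied to unseen data (streaming mode).
#'
#' @param ext an [extend_emg()] result.
#' @param reg_floor optional explicit eigenvalue floor; components with
#'   eigenvalue `<=` the floor are discarded.
#' @return An `ext_whitened`: `whitened` (retained x samples), `W`
#'   (whitening matrix, retained x `m * R`), `row_means`, `retained_dims`,
#'   plus the extension metadata.
#' @export
whiten_emg <- function(ext, reg_floor = NULL) {
  stopifnot(inherits(ext, "ext_signal"))
  E <- ext$extended
  if (ncol(E) <= nrow(E))
    warn("fewer samples than extended dimensions; whitening will be rank-limited")
  mu <- rowMeans(E)
  E <- E - mu
  if (all(abs(E) < .Machine$double.eps))
    abort("zero-variance input", class = "mudecomp_degenerate_signal")
  C <- tcrossprod(E) / ncol(E)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (is.null(reg_floor)) {
    half <- ev[seq.int(ceiling(length(ev) / 2) + 1L, length(ev))]
    reg_floor <- mean(half)
  }
  keep <- ev > reg_floor
  if (!any(keep))
    abort("no components above the regularisation floor",
          class = "mudecomp_degenerate_signal")
  W <- t(eg$vectors[, keep, drop = FALSE]) / sqrt(ev[keep])
  structure(list(whitened = W %*% E, W = W, row_means = mu,
                 retained_dims = sum(keep), eigenvalues = ev,
                 R = ext$R, m = ext$m, sampling_rate = ext$sampling_rate,
                 mask_applied = ext$mask_applied),
            class = "ext_whitened")
}

#' Re-apply a stored whitening transform
#'
#' @param xw an [whiten_emg()] result (provides `W` and `row_means`).
#' @param extended an extended matrix with `m * R` rows.
#' @return whitened matrix, retained x samples.
#' @export
whiten_apply <- function(xw, extended) {
  stopifnot(inherits(xw, "ext_whitened"))
  if (nrow(extended) != ncol(xw$W))
    abort("extended row count does not match the whitening matrix",
          class = "mudecomp_invalid_argument")
  xw$W %*% (extended - xw$row_means)
}

#' @export
print.ext_whitened <- function(x, ...) {
  cat(sprintf("<ext_whitened> %d/%d dims retained (m = %d, R = %d), %d samples\n",
              x$retained_dims, x$m * x$R, x$m, x$R, ncol(x$whitened)))
  invisible(x)
}
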