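#' EMG recording container
#'
#' Channels x samples matrix with its sampling rate, array geometry and a
#' per-channel boolean mask (`TRUE` = retained).
#'
#' @param data numeric matrix, channels x samples.
#' @param sampling_rate Hz.
#' @param array an [electrode_array()] or `NULL`.
#' @param mask logical vector, one entry per channel.
#' @param meta free-form metadata list.
#' @return An `emg_recording`.
#' @export
new_emg_recording <- function(data, sampling_rate, array = NULL,
                              mask = rep(TRUE, nrow(data)), meta = list()) {
  data <- as.matrix(data)
  if (nrow(data) < 1 || ncol(data) < 1)
    abort("recording needs at least one channel and one sample",
          class = "mudecomp_invalid_argument")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    abort("sampling_rate must be positive", class = "mudecomp_invalid_argument")
  if (length(mask) != nrow(data))
    abort("mask length must equal the channel count",
          class = "mudecomp_invalid_argument")
  structure(list(data = data, sampling_rate = sampling_rate, array = array,
                 mask = as.logical(mask), meta = meta),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples (%.2f s at %g Hz), %d masked\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$sampling_rate,
              x$sampling_rate, sum(!x$mask)))
  invisible(x)
}

#' Apply an electrode mask
#'
#' Removes the channels flagged `FALSE`; the mask is persisted in the
#' recording metadata so it can be reused across a session (see
#' [write_mask()]).
#'
#' @param rec an `emg_recording`.
#' @param mask logical vector of length equal to the recording's channel
#'   count (`TRUE` = keep).
#' @return The masked `emg_recording`.
#' @export
apply_mask <- function(rec, mask = rec$mask) {
  stopifnot(inherits(rec, "emg_recording"))
  if (length(mask) != nrow(rec$data))
    abort(sprintf("mask length %d does not match channel count %d",
                  length(mask), nrow(rec$data)),
          class = "mudecomp_mask_mismatch")
  mask <- as.logical(mask)
  if (!any(mask))
    abort("all channels masked", class = "mudecomp_empty_recording")
  out <- rec
  out$data <- rec$data[mask, , drop = FALSE]
  out$mask <- rep(TRUE, sum(mask))
  out$meta$mask_applied <- mask
  out
}

#' @describeIn new_emg_recording decimated multichannel trace plot.
#' @param object an `emg_recording`.
#' @param channels channels to draw.
#' @param ... unused.
#' @export
autoplot.emg_recording <- function(object, channels = seq_len(min(8, nrow(object$data))), ...) {
  dec <- max(1L, floor(ncol(object$data) / 4000))
  idx <- seq(1L, ncol(object$data), by = dec)
  spread <- 3 * stats::median(apply(object$data[channels, , drop = FALSE], 1, sd))
  df <- purrr::map_dfr(seq_along(channels), function(k) {
    ch <- channels[k]
    tibble::tibble(time_s = idx / object$sampling_rate,
                   value = object$data[ch, idx] + (k - 1) * spread,
                   channel = factor(ch))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value, group = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "EMG (offset per channel)")
}
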