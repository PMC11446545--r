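#' Initialise a real-time decoding stream
#'
#' Freezes the calibration artifacts of an offline decomposition (electrode
#' mask, extension factor, whitening matrix and row means, per-unit
#' separation vectors and spike/noise centroids) into a stream state that
#' [process_epoch()] updates in place. Each separation vector is folded with
#' the whitening matrix into a single projection vector in extended signal
#' space, so an epoch is processed as: mask, extend with the carried
#' `R - 1` raw samples, project, square, causal peak detection with the
#' 25 ms separation enforced across epoch boundaries, nearest-centroid
#' spike/noise classification.
#'
#' @param decomp a [decompose_offline()] result (or a path readable by
#'   [read_filters()]).
#' @param n_channels channel count of the incoming stream; must match the
#'   calibration mask length.
#' @param config a [mu_config()].
#' @return A `stream_state` environment.
#' @export
init_stream <- function(decomp, n_channels = NULL, config = mu_config()) {
  if (is.character(decomp)) decomp <- read_filters(decomp)
  stopifnot(inherits(decomp, "mu_decomposition"))
  cal <- decomp$calibration
  if (!is.null(n_channels) && n_channels != length(cal$mask))
    abort(sprintf("stream has %d channels but filters were calibrated on %d",
                  n_channels, length(cal$mask)),
          class = "mudecomp_calibration_mismatch")
  if (!length(decomp$filters))
    abort("decomposition has no accepted filters",
          class = "mudecomp_invalid_argument")
  rt <- config$realtime
  fs <- cal$sampling_rate
  st <- new.env(parent = emptyenv())
  st$filters <- decomp$filters
  st$n_units <- length(decomp$filters)
  st$mask <- cal$mask
  st$R <- cal$R
  st$W <- cal$W
  st$row_means <- cal$row_means
  st$sampling_rate <- fs
  st$m <- cal$m
  st$epoch_samples <- round(rt$epoch_ms / 1000 * fs)
  st$sep <- round(config$decomposition$min_separation_ms / 1000 * fs)
  st$rate_window <- rt$rate_window_epochs
  st$rate_smooth <- rt$rate_smooth_values
  st$version <- 1L
  stream_reset(st)
  stream_fold_filters(st)
  class(st) <- c("stream_state", "environment")
  st
}

# fold whitening into per-unit extended-space projection vectors
stream_fold_filters <- function(st) {
  wmat <- vapply(st$filters, `[[`, numeric(nrow(st$W)), "w")
  st$C <- crossprod(st$W, wmat)                 # (m R) x n_units
  st$offsets <- as.vector(crossprod(st$C, st$row_means))
  st$centroids <- cbind(spike = vapply(st$filters, `[[`, 1, "spike_centroid"),
                        noise = vapply(st$filters, `[[`, 1, "noise_centroid"))
  invisible(st)
}

stream_reset <- function(st) {
  st$carry_raw <- matrix(0, st$m, st$R - 1L)
  st$peak_states <- replicate(st$n_units, new_peak_state(), simplify = FALSE)
  st$counts <- matrix(0L, st$n_units, 0)
  st$raw_rates <- matrix(0, st$n_units, 0)
  st$epoch_index <- 0L
  st$spikes <- vector("list", st$n_units)
  invisible(st)
}

#' @export
print.stream_state <- function(x, ...) {
  cat(sprintf("<stream_state> %d motor units, %d-sample epochs at %g Hz (v%d), epoch %d\n",
              x$n_units, x$epoch_samples, x$sampling_rate, x$version,
              x$epoch_index))
  invisible(x)
}

#' Process one streamed epoch
#'
#' Applies the frozen motor unit filters to a raw epoch (all channels,
#' including masked ones) and returns the discharges classified as spikes,
#' with absolute sample indices, plus smoothed firing rates. The 25 ms peak
#' separation is enforced across epoch boundaries by holding back an
#' unprocessed tail, so a discharge close to an epoch's end may be reported
#' with the following epoch.
#'
#' @param st a [init_stream()] state (updated in place).
#' @param epoch numeric matrix, channels x `epoch_samples`.
#' @return An `epoch_result`: `epoch_index`, `spikes` tibble (`unit`,
#'   `sample`, `time_s`), `rates` tibble (`unit`, `rate_raw`,
#'   `rate_smooth`).
#' @export
process_epoch <- function(st, epoch) {
  stopifnot(inherits(st, "stream_state"))
  epoch <- as.matrix(epoch)
  if (nrow(epoch) != length(st$mask))
    abort("epoch channel count does not match the calibration mask",
          class = "mudecomp_calibration_mismatch")
  if (ncol(epoch) != st$epoch_samples)
    abort(sprintf("epoch must have %d samples, got %d",
                  st$epoch_samples, ncol(epoch)),
          class = "mudecomp_invalid_epoch")
  st$epoch_index <- st$epoch_index + 1L
  abs_start <- (st$epoch_index - 1L) * st$epoch_samples + 1L
  sp <- stream_project(st, epoch[st$mask, , drop = FALSE], abs_start,
                       flush = FALSE)
  epoch_result(st, sp)
}

# shared projection + detection; x is the masked epoch (m x n)
stream_project <- function(st, x, abs_start, flush = FALSE) {
  n <- ncol(x)
  out_unit <- integer(0); out_sample <- integer(0)
  if (n > 0) {
    seg <- cbind(st$carry_raw, x)
    E <- extend_matrix(seg, st$R)
    E <- E[, st$R:ncol(seg), drop = FALSE]       # columns for the new samples
    S2 <- (crossprod(st$C, E) - st$offsets)^2
    if (st$R > 1L)
      st$carry_raw <- seg[, (ncol(seg) - st$R + 2L):ncol(seg), drop = FALSE]
  }
  for (u in seq_len(st$n_units)) {
    vals <- if (n > 0) S2[u, ] else numeric(0)
    ps <- st$peak_states[[u]]
    if (ps$buf_start + length(ps$buf) == 1L) ps$buf_start <- abs_start
    res <- peak_step(ps, vals, st$sep, flush = flush)
    st$peak_states[[u]] <- res$state
    if (nrow(res$peaks)) {
      a <- res$peaks$amplitude
      is_spike <- abs(a - st$centroids[u, "spike"]) <
                  abs(a - st$centroids[u, "noise"])
      smp <- res$peaks$sample[is_spike]
      if (length(smp)) {
        st$spikes[[u]] <- c(st$spikes[[u]], smp)
        out_unit <- c(out_unit, rep(u, length(smp)))
        out_sample <- c(out_sample, smp)
      }
    }
  }
  tibble::tibble(unit = out_unit, sample = out_sample)
}

epoch_result <- function(st, sp) {
  # assign finalized spikes to the epoch they occurred in, then update rates
  k <- st$epoch_index
  counts_new <- integer(st$n_units)
  if (nrow(sp)) {
    ep_of <- (sp$sample - 1L) %/% st$epoch_samples + 1L
    for (i in seq_len(nrow(sp))) {
      e <- min(ep_of[i], k)
      if (e == k) counts_new[sp$unit[i]] <- counts_new[sp$unit[i]] + 1L
      else st$counts[sp$unit[i], e] <- st$counts[sp$unit[i], e] + 1L
    }
  }
  rates <- update_rates(st, counts_new)
  structure(list(epoch_index = k,
                 spikes = dplyr::mutate(sp, time_s = .data$sample / st$sampling_rate),
                 rates = rates),
            class = "epoch_result")
}

#' Update smoothed firing rates
#'
#' Appends one epoch's spike counts to the stream state and returns the raw
#' rate (spike count over the trailing window of 8 x 125 ms epochs, i.e.
#' spikes in the trailing second, directly in pps) and the smoothed rate
#' (mean of the last 4 raw values, a 500 ms smoothing of the feedback path).
#'
#' @param st a [init_stream()] state.
#' @param epoch_spike_counts integer vector, one count per unit.
#' @return tibble with `unit`, `rate_raw`, `rate_smooth`.
#' @export
update_rates <- function(st, epoch_spike_counts) {
  stopifnot(inherits(st, "stream_state"),
            length(epoch_spike_counts) == st$n_units)
  st$counts <- cbind(st$counts, as.integer(epoch_spike_counts))
  k <- ncol(st$counts)
  win <- max(1L, k - st$rate_window + 1L):k
  raw <- rowSums(st$counts[, win, drop = FALSE])
  st$raw_rates <- cbind(st$raw_rates, raw)
  swin <- max(1L, k - st$rate_smooth + 1L):k
  sm <- rowMeans(st$raw_rates[, swin, drop = FALSE])
  tibble::tibble(unit = seq_len(st$n_units), rate_raw = as.numeric(raw),
                 rate_smooth = sm)
}

#' Finalise a stream
#'
#' Flushes the held-back tail at the end of a recording, emitting any pending
#' peaks.
#'
#' @param st a stream state.
#' @return tibble of remaining spikes (`unit`, `sample`).
#' @export
finalize_stream <- function(st) {
  stopifnot(inherits(st, "stream_state"))
  abs_start <- st$epoch_index * st$epoch_samples + 1L
  sp <- stream_project(st, matrix(0, st$m, 0), abs_start, flush = TRUE)
  if (nrow(sp)) {
    ep_of <- pmin((sp$sample - 1L) %/% st$epoch_samples + 1L, ncol(st$counts))
    for (i in seq_len(nrow(sp)))
      st$counts[sp$unit[i], ep_of[i]] <- st$counts[sp$unit[i], ep_of[i]] + 1L
  }
  sp
}

#' Stream a whole recording through the real-time path
#'
#' File-replay streamer: cuts the recording into consecutive 125 ms epochs,
#' feeds them through [process_epoch()], flushes the tail, and collects
#' discharges and rates. A trailing partial epoch is discarded, as in
#' packet-based acquisition.
#'
#' @param rec an [new_emg_recording()].
#' @param decomp a [decompose_offline()] result (or an existing
#'   `stream_state` to continue).
#' @param config a [mu_config()].
#' @return A `stream_result`: `spikes` tibble (`unit`, `sample`, `time_s`,
#'   `epoch`), `rates` tibble (`epoch`, `unit`, `rate_raw`, `rate_smooth`),
#'   `spike_trains` list, `n_epochs`, and the state.
#' @export
stream_recording <- function(rec, decomp, config = mu_config()) {
  stopifnot(inherits(rec, "emg_recording"))
  st <- if (inherits(decomp, "stream_state")) decomp
        else init_stream(decomp, n_channels = nrow(rec$data), config = config)
  if (rec$sampling_rate != st$sampling_rate)
    abort("recording and calibration sampling rates differ",
          class = "mudecomp_calibration_mismatch")
  n_epochs <- ncol(rec$data) %/% st$epoch_samples
  spikes <- vector("list", n_epochs)
  rates <- vector("list", n_epochs)
  for (k in seq_len(n_epochs)) {
    cols <- ((k - 1L) * st$epoch_samples + 1L):(k * st$epoch_samples)
    er <- process_epoch(st, rec$data[, cols, drop = FALSE])
    spikes[[k]] <- dplyr::mutate(er$spikes, epoch = k)
    rates[[k]] <- dplyr::mutate(er$rates, epoch = k)
  }
  tail_sp <- finalize_stream(st)
  if (nrow(tail_sp))
    spikes[[n_epochs + 1L]] <- dplyr::mutate(
      tail_sp, time_s = .data$sample / st$sampling_rate, epoch = n_epochs)
  sp <- dplyr::bind_rows(spikes) |> dplyr::arrange(.data$unit, .data$sample)
  trains <- lapply(seq_len(st$n_units),
                   function(u) as.integer(sort(sp$sample[sp$unit == u])))
  names(trains) <- paste0("unit_", seq_len(st$n_units))
  structure(list(spikes = sp, rates = dplyr::bind_rows(rates),
                 spike_trains = trains, n_epochs = n_epochs, state = st),
            class = "stream_result")
}

#' @export
print.stream_result <- function(x, ...) {
  cat(sprintf("<stream_result> %d epochs, %d units, %d discharges\n",
              x$n_epochs, length(x$spike_trains), nrow(x$spikes)))
  invisible(x)
}

#' @describeIn stream_recording per-discharge tibble.
#' @param x,object a `stream_result`.
#' @param ... unused.
#' @export
tidy.stream_result <- function(x, ...) x$spikes

#' @describeIn stream_recording smoothed-rate traces per unit.
#' @export
autoplot.stream_result <- function(object, ...) {
  ggplot2::ggplot(object$rates,
                  ggplot2::aes(.data$epoch, .data$rate_smooth,
                               colour = factor(.data$unit))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch (125 ms)", y = "smoothed rate (pps)",
                  colour = "unit")
}

#' Batch re-application of frozen filters
#'
#' Applies the calibration filters to a whole recording in one pass (mask,
#' full-record extension, projection, squared pulse train, causal peak
#' detection, nearest-centroid classification). This is the offline
#' counterpart of [stream_recording()]; for any recording the two produce
#' identical discharge sets, which is the central streaming invariant.
#'
#' @param rec an [new_emg_recording()].
#' @param decomp a [decompose_offline()] result.
#' @param config a [mu_config()].
#' @param n_samples restrict to the first `n_samples` samples (default: the
#'   whole-epoch portion, matching the streamer).
#' @return list of spike trains (sample indices), one per unit.
#' @export
apply_filters <- function(rec, decomp, config = mu_config(), n_samples = NULL) {
  stopifnot(inherits(rec, "emg_recording"), inherits(decomp, "mu_decomposition"))
  cal <- decomp$calibration
  if (nrow(rec$data) != length(cal$mask))
    abort("recording channel count does not match the calibration mask",
          class = "mudecomp_calibration_mismatch")
  fs <- rec$sampling_rate
  esamp <- round(config$realtime$epoch_ms / 1000 * fs)
  n_samples <- n_samples %||% (ncol(rec$data) %/% esamp) * esamp
  x <- rec$data[cal$mask, seq_len(n_samples), drop = FALSE]
  E <- extend_matrix(x, cal$R)
  wmat <- vapply(decomp$filters, `[[`, numeric(nrow(cal$W)), "w")
  C <- crossprod(cal$W, wmat)
  offsets <- as.vector(crossprod(C, cal$row_means))
  S2 <- (crossprod(C, E) - offsets)^2
  sep <- round(config$decomposition$min_separation_ms / 1000 * fs)
  trains <- lapply(seq_along(decomp$filters), function(u) {
    pk <- causal_peaks(S2[u, ], sep)
    if (!nrow(pk)) return(integer(0))
    f <- decomp$filters[[u]]
    keep <- abs(pk$amplitude - f$spike_centroid) <
            abs(pk$amplitude - f$noise_centroid)
    pk$sample[keep]
  })
  names(trains) <- paste0("unit_", seq_along(trains))
  trains
}

#' Recalibrate a stream during a rest period
#'
#' Recomputes the whitening from a rest-period recording and every unit's
#' filter as the spike-triggered average over the supplied (manually edited)
#' trains, together with fresh spike/noise centroids. Units whose new
#' silhouette falls below the gate keep their previous filter (with a
#' warning). Buffers are reset and the state version incremented.
#'
#' @param st a stream state.
#' @param rest_recording an [new_emg_recording()] covering the rest-period
#'   baseline.
#' @param edited_trains list of spike trains (sample indices in the rest
#'   recording), one per unit.
#' @param config a [mu_config()].
#' @return the updated state, invisibly.
#' @export
recalibrate <- function(st, rest_recording, edited_trains, config = mu_config()) {
  stopifnot(inherits(st, "stream_state"))
  if (!inherits(rest_recording, "emg_recording") || ncol(rest_recording$data) < 1)
    abort("empty rest recording", class = "mudecomp_invalid_argument")
  if (nrow(rest_recording$data) != length(st$mask))
    abort("rest recording channel count does not match the calibration mask",
          class = "mudecomp_calibration_mismatch")
  if (length(edited_trains) != st$n_units)
    abort("need one edited train per unit", class = "mudecomp_invalid_argument")
  masked <- rest_recording
  masked$data <- rest_recording$data[st$mask, , drop = FALSE]
  masked$mask <- rep(TRUE, sum(st$mask))
  xw <- whiten_emg(extend_emg(masked, st$R))
  thr <- config$decomposition$sil_threshold
  sepms <- config$decomposition$min_separation_ms
  new_filters <- st$filters
  for (u in seq_len(st$n_units)) {
    tr <- edited_trains[[u]]
    upd <- tryCatch({
      if (length(tr) < 2) stop("too few spikes")
      w <- rowMeans(xw$whitened[, tr, drop = FALSE])
      w <- w / sqrt(sum(w^2))
      s2 <- as.vector(crossprod(w, xw$whitened))^2
      pt <- detect_and_classify_peaks(s2, st$sampling_rate, sepms)
      sil <- compute_sil(pt)
      if (sil < thr) stop(sprintf("SIL %.3f below gate", sil))
      f <- new_filters[[u]]
      f$w <- as.vector(w)
      f$spike_centroid <- pt$spike_centroid
      f$noise_centroid <- pt$noise_centroid
      f$sil <- sil
      f
    }, error = function(e) {
      warn(sprintf("unit %d kept at previous calibration: %s", u,
                   conditionMessage(e)))
      NULL
    })
    if (!is.null(upd)) new_filters[[u]] <- upd
  }
  st$filters <- new_filters
  st$W <- xw$W
  st$row_means <- xw$row_means
  st$version <- st$version + 1L
  stream_reset(st)
  stream_fold_filters(st)
  invisible(st)
}

#' Build a feedback frame from an epoch result
#'
#' Serialisable visual-feedback payloads: `raster` (per-unit discharge
#' samples of this epoch), `quadrant` (the smoothed rates of exactly two
#' selected units as one 2D point per 125 ms window) or `rate_path` (the
#' smoothed rate of one selected unit).
#'
#' @param result a [process_epoch()] `epoch_result`.
#' @param mode `"raster"`, `"quadrant"` or `"rate_path"`.
#' @param units selected unit ids (`quadrant` needs exactly 2, `rate_path`
#'   exactly 1; `raster` defaults to all).
#' @return a named list (JSON-ready frame).
#' @export
feedback_values <- function(result, mode = c("raster", "quadrant", "rate_path"),
                            units = NULL) {
  stopifnot(inherits(result, "epoch_result"))
  mode <- match.arg(mode)
  if (mode == "raster") {
    sel <- units %||% unique(result$rates$unit)
    sp <- result$spikes[result$spikes$unit %in% sel, ]
    list(mode = "raster", epoch = result$epoch_index,
         spikes = split(sp$sample, factor(sp$unit, levels = sel)))
  } else if (mode == "quadrant") {
    if (length(units) != 2)
      abort("quadrant feedback needs exactly 2 units",
            class = "mudecomp_invalid_selection")
    r <- result$rates$rate_smooth[match(units, result$rates$unit)]
    list(mode = "quadrant", epoch = result$epoch_index,
         units = units, point = c(r[1], r[2]))
  } else {
    if (length(units) != 1)
      abort("rate_path feedback needs exactly 1 unit",
            class = "mudecomp_invalid_selection")
    list(mode = "rate_path", epoch = result$epoch_index, unit = units,
         rate = result$rates$rate_smooth[match(units, result$rates$unit)])
  }
}
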