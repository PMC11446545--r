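#' Simulate a closed-loop isometric contraction
#'
#' Runs the per-sample loop of the pool model: a PID controller adjusts a
#' scalar excitatory drive to minimise the error between the target force and
#' the force generated by the active units; units whose recruitment threshold
#' is at or below the drive fire with mean rate
#' `min_rate + rate_gain * (drive - threshold)` capped at `peak_rate`, with
#' Gaussian interspike-interval jitter of coefficient `isi_cov`; force is the
#' superposition of the twitch responses (`A * t/Tc * exp(1 - t/Tc)`) to every
#' discharge, normalised so that 100% MVC is the analytic steady-state force
#' at maximal drive.
#'
#' @param pool a [build_motor_unit_pool()] pool.
#' @param profile a [generate_force_profile()] target.
#' @param gains PID gains `list(kp, ki, kd)`; defaults from [mu_config()].
#' @param seed integer seed for the interspike-interval jitter.
#' @param drive optional per-sample drive trace; when supplied the PID loop is
#'   bypassed (open-loop mode, used for oracle checks).
#' @param config a [mu_config()].
#' @return A `sim_truth` object: `spike_trains` (list of strictly increasing
#'   1-based sample indices per unit), `force` and `drive` traces, the target,
#'   and the sampling rate.
#' @export
simulate_contraction <- function(pool, profile, gains = NULL, seed = NULL,
                                 drive = NULL, config = mu_config()) {
  stopifnot(inherits(pool, "motor_unit_pool"), inherits(profile, "force_profile"))
  gains <- gains %||% config$simulator$pid
  if (!is.null(seed)) set.seed(seed)
  u <- pool$units
  fs <- profile$sampling_rate
  fmax <- pool_max_force(pool)
  # blow-up guard: force past twice the peak target means the controller has
  # lost the plant (firing-rate saturation makes an absolute % MVC ceiling
  # unreachable, so the guard is relative to the task)
  f_limit <- if (is.null(drive)) max(2 * max(profile$target), 10) else Inf
  res <- contraction_loop(profile$target, 1 / fs,
                          u$threshold, pool$min_rate, pool$rate_gain,
                          pool$peak_rate, u$twitch_amplitude,
                          u$twitch_contraction_time, pool$isi_cov,
                          gains$kp, gains$ki, gains$kd,
                          drive %||% numeric(0), fmax,
                          config$simulator$drive_max, f_limit)
  if (isTRUE(res$diverged))
    abort("force diverged beyond twice the peak target; PID gains unstable",
          class = "mudecomp_simulation_diverged")
  names(res$spikes) <- paste0("unit_", u$unit)
  structure(list(spike_trains = res$spikes, force = res$force,
                 drive = res$drive, target = profile$target,
                 sampling_rate = fs, n_units = pool$n_units,
                 seed = seed),
            class = "sim_truth")
}

# analytic steady-state force at drive = 1: each active unit contributes
# amplitude * rate * e * Tc (the twitch time-integral is e * Tc)
pool_max_force <- function(pool) {
  u <- pool$units
  rate <- pmin(pool$min_rate + pool$rate_gain * (1 - u$threshold), pool$peak_rate)
  sum(u$twitch_amplitude * rate * exp(1) * u$twitch_contraction_time)
}

#' @export
print.sim_truth <- function(x, ...) {
  act <- sum(vapply(x$spike_trains, length, 1L) > 0)
  cat(sprintf("<sim_truth> %d/%d units active, %.1f s at %g Hz, %d discharges\n",
              act, x$n_units, length(x$force) / x$sampling_rate,
              x$sampling_rate, sum(vapply(x$spike_trains, length, 1L))))
  invisible(x)
}

#' @describeIn simulate_contraction one row per ground-truth discharge
#'   (`unit`, `sample`, `time_s`).
#' @param x,object a `sim_truth`.
#' @param ... unused.
#' @export
tidy.sim_truth <- function(x, ...) {
  purrr::imap_dfr(x$spike_trains, function(sp, nm) {
    tibble::tibble(unit = as.integer(sub("unit_", "", nm)), sample = sp)
  }) |>
    dplyr::mutate(time_s = .data$sample / x$sampling_rate) |>
    dplyr::arrange(.data$unit, .data$sample)
}

#' @describeIn simulate_contraction one-row summary (active units, discharge
#'   count, force tracking error on the record).
#' @export
glance.sim_truth <- function(x, ...) {
  tibble::tibble(
    n_units = x$n_units,
    n_active = sum(vapply(x$spike_trains, length, 1L) > 0),
    n_discharges = sum(vapply(x$spike_trains, length, 1L)),
    duration_s = length(x$force) / x$sampling_rate,
    mean_abs_error_pct = mean(abs(x$force - x$target))
  )
}

#' @describeIn simulate_contraction raster plot of ground-truth discharges.
#' @export
autoplot.sim_truth <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$unit)) +
    ggplot2::geom_point(shape = "|", size = 1.5) +
    ggplot2::labs(x = "time (s)", y = "motor unit (recruitment order)")
}

#' Mean absolute force-tracking error on the plateau
#'
#' Helper for regression-testing the controller: mean absolute difference
#' between produced and target force (% MVC), skipping the first
#' `settle_s` seconds of the window where the target is at its plateau value.
#'
#' @param truth a `sim_truth`.
#' @param settle_s settling time excluded from the start of the plateau, s.
#' @return scalar, % MVC.
#' @export
plateau_tracking_error <- function(truth, settle_s = 1) {
  lev <- max(truth$target)
  idx <- which(truth$target == lev)
  idx <- idx[idx > min(idx) + settle_s * truth$sampling_rate]
  mean(abs(truth$force[idx] - truth$target[idx]))
}
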