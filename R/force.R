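#' Generate a target force profile
#'
#' Trapezoid: linear ramp up, constant plateau, linear ramp down. Sinusoid:
#' `centre + amplitude * sin(2 * pi * f * t)`; the defaults oscillate between
#' 15 and 25% MVC at 0.5 Hz.
#'
#' @param kind `"trapezoid"` or `"sinusoid"`.
#' @param sampling_rate Hz.
#' @param ramp_duration,plateau_duration trapezoid phase durations, s.
#' @param plateau_level trapezoid plateau, % MVC.
#' @param sine_centre,sine_amplitude sinusoid centre and amplitude, % MVC.
#' @param sine_frequency Hz.
#' @param duration sinusoid total duration, s.
#' @return A `force_profile` with the per-sample target series (% MVC).
#' @examples
#' fp <- generate_force_profile("trapezoid", plateau_level = 20)
#' range(fp$target)
#' @export
generate_force_profile <- function(kind = c("trapezoid", "sinusoid"),
                                   sampling_rate = 2048,
                                   ramp_duration = 5, plateau_duration = 20,
                                   plateau_level = 20,
                                   sine_centre = 20, sine_amplitude = 5,
                                   sine_frequency = 0.5, duration = 30) {
  kind <- match.arg(kind)
  if (sampling_rate <= 0)
    abort("sampling_rate must be positive", class = "mudecomp_invalid_argument")
  if (kind == "trapezoid") {
    if (ramp_duration < 0 || plateau_duration <= 0 || plateau_level < 0)
      abort("durations must be non-negative and plateau_duration positive, levels >= 0",
            class = "mudecomp_invalid_argument")
    nr <- round(ramp_duration * sampling_rate)
    np <- round(plateau_duration * sampling_rate)
    up <- if (nr > 0) plateau_level * seq_len(nr) / nr else numeric(0)
    target <- c(up, rep(plateau_level, np), rev(up))
  } else {
    if (duration <= 0 || sine_amplitude < 0 || sine_centre - sine_amplitude < 0)
      abort("sinusoid must have positive duration and non-negative targets",
            class = "mudecomp_invalid_argument")
    t <- seq_len(round(duration * sampling_rate)) / sampling_rate
    target <- sine_centre + sine_amplitude * sin(2 * pi * sine_frequency * t)
  }
  structure(list(kind = kind, target = target, sampling_rate = sampling_rate,
                 params = list(ramp_duration = ramp_duration,
                               plateau_duration = plateau_duration,
                               plateau_level = plateau_level,
                               sine_centre = sine_centre,
                               sine_amplitude = sine_amplitude,
                               sine_frequency = sine_frequency)),
            class = "force_profile")
}

#' @export
print.force_profile <- function(x, ...) {
  cat(sprintf("<force_profile> %s, %.1f s at %g Hz, range %.1f-%.1f %%MVC\n",
              x$kind, length(x$target) / x$sampling_rate, x$sampling_rate,
              min(x$target), max(x$target)))
  invisible(x)
}

#' @export
autoplot.force_profile <- function(object, ...) {
  df <- tibble::tibble(time_s = seq_along(object$target) / object$sampling_rate,
                       target = object$target)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$target)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "target force (% MVC)")
}
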