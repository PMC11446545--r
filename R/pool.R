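#' Build a motor unit pool
#'
#' Distributes `n_units` motor unit territories uniformly over the muscle
#' cross-section and assigns each unit an innervation number (truncated
#' exponential over 66-3321 fibres), a territory area (0.8-78.5 mm^2, scaled
#' with innervation), a recruitment threshold (exponential distribution with a
#' 30-fold range, expressed as a fraction of the maximal drive), rate-coding
#' parameters (minimum rate + linear gain with excess drive, capped at the
#' peak rate) and twitch parameters (amplitude proportional to innervation
#' number, contraction time 30-100 ms, inversely related to amplitude).
#' Units are ordered by recruitment threshold (size principle: small,
#' low-threshold units first).
#'
#' @param n_units number of motor units (>= 1).
#' @param anatomy a [muscle_anatomy()].
#' @param seed integer seed; fixed seeds give bit-identical pools.
#' @param threshold_max recruitment threshold of the last-recruited unit, as a
#'   fraction of maximal drive.
#' @param min_rate,peak_rate minimum and peak firing rates, pps.
#' @param rate_gain firing-rate gain, pps per unit of excess drive.
#' @param isi_cov coefficient of variation of the interspike-interval jitter.
#' @return A `motor_unit_pool`: scalars plus a `units` tibble with one row per
#'   unit (`unit`, `x`, `y`, `innervation`, `area`, `threshold`,
#'   `twitch_amplitude`, `twitch_contraction_time`).
#' @examples
#' pool <- build_motor_unit_pool(20, seed = 1)
#' pool$units
#' @export
build_motor_unit_pool <- function(n_units = 150, anatomy = muscle_anatomy(),
                                  seed = NULL, threshold_max = 0.8,
                                  min_rate = 8, peak_rate = 35,
                                  rate_gain = 40, isi_cov = 0.15) {
  if (!is.numeric(n_units) || n_units < 1)
    abort("n_units must be >= 1", class = "mudecomp_invalid_argument")
  n_units <- as.integer(n_units)
  if (!is.null(seed)) set.seed(seed)

  # territory centres: uniform over the muscle cross-section disc
  r <- anatomy$muscle_radius * sqrt(runif(n_units))
  th <- runif(n_units, 0, 2 * pi)
  x <- r * cos(th); y <- r * sin(th)

  innervation <- rtrunc_exp(n_units, 66, 3321)

  # order by innervation so thresholds follow the size principle
  o <- order(innervation)
  x <- x[o]; y <- y[o]; innervation <- innervation[o]

  area <- 0.8 + (innervation - 66) / (3321 - 66) * (78.5 - 0.8)
  i <- seq_len(n_units)
  threshold <- threshold_max * 30^(i / n_units) / 30
  twitch_amplitude <- innervation
  frac <- if (n_units > 1) (i - 1) / (n_units - 1) else 0
  twitch_contraction_time <- 0.100 - 0.070 * frac  # s; 100 ms -> 30 ms

  structure(list(
    n_units = n_units,
    anatomy = anatomy,
    min_rate = min_rate, peak_rate = peak_rate,
    rate_gain = rate_gain, isi_cov = isi_cov,
    units = tibble::tibble(
      unit = i, x = x, y = y,
      innervation = innervation, area = area, threshold = threshold,
      twitch_amplitude = twitch_amplitude,
      twitch_contraction_time = twitch_contraction_time
    )
  ), class = "motor_unit_pool")
}

# draws from an exponential distribution truncated to [a, b]; the scale is
# (b - a) / log(b / a), giving the many-small / few-large innervation profile
rtrunc_exp <- function(n, a, b, scale = (b - a) / log(b / a)) {
  u <- runif(n)
  a - scale * log(1 - u * (1 - exp(-(b - a) / scale)))
}

#' @export
print.motor_unit_pool <- function(x, ...) {
  cat(sprintf("<motor_unit_pool> %d units, muscle radius %g mm\n",
              x$n_units, x$anatomy$muscle_radius))
  cat(sprintf("  innervation %d-%d fibres, thresholds %.3f-%.3f of max drive\n",
              round(min(x$units$innervation)), round(max(x$units$innervation)),
              min(x$units$threshold), max(x$units$threshold)))
  invisible(x)
}
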