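#' Synthesise motor unit action potential templates
#'
#' Surrogate volume-conductor model. Each unit's action potential is the
#' superposition of 8 fibre-cluster sub-sources scattered over its territory,
#' each a Hermite-Rodriguez waveform (biphasic or triphasic, chosen per unit)
#' whose amplitude scales as innervation^0.7 and decays with the
#' source-electrode distance `d` as `(d + d0)^-p` (p = 2.5 for surface grids,
#' 3 for intramuscular arrays, d0 = 1 mm), whose duration broadens with
#' distance as `1 + d / 10 mm`, and which propagates in both directions from
#' the unit's innervation zone (offset up to +/- 6 mm along the array) with a
#' conduction velocity drawn uniformly in 3-5 m/s, extinguishing at the fibre
#' ends (semi-length 15-25 mm). End-plate scatter grows with territory size,
#' dispersing the potentials of large late-recruited units. This preserves
#' the properties the separation algorithm relies on: a unique multichannel
#' spatial profile per unit and distance-dependent tissue filtering (a unit
#' close to the intramuscular array has appreciable amplitude on only a few
#' neighbouring electrodes, surface potentials span many).
#'
#' @param pool a [build_motor_unit_pool()] pool.
#' @param anatomy a [muscle_anatomy()].
#' @param array an [electrode_array()].
#' @param sampling_rate Hz; defaults to the array's rate.
#' @param seed integer seed.
#' @param duration_ms template support, ms (default 30 surface / 10
#'   intramuscular).
#' @return A `muap_templates` object with `templates`
#'   (n_units x n_channels x L array), `duration_L`, per-unit
#'   `conduction_velocity`, and channel positions.
#' @export
synthesize_muap_templates <- function(pool, anatomy = muscle_anatomy(),
                                      array = electrode_array("surface_grid"),
                                      sampling_rate = array$sampling_rate,
                                      seed = NULL, duration_ms = NULL) {
  stopifnot(inherits(pool, "motor_unit_pool"), inherits(array, "electrode_array"))
  if (!is.null(seed)) set.seed(seed)
  surface <- array$kind == "surface_grid"
  pos <- array_positions(array, anatomy)
  n_ch <- nrow(pos)
  duration_ms <- duration_ms %||% if (surface) 30 else 10
  L <- round(duration_ms / 1000 * sampling_rate)
  p <- if (surface) 2.5 else 3
  d0 <- 1
  u <- pool$units
  n <- pool$n_units

  # each unit's action potential is the superposition of n_src fibre-cluster
  # sub-sources scattered over its territory (end-plate scatter as a small
  # temporal jitter), which gives every unit a unique spatial signature
  n_src <- 8L
  draw_unit <- function(i) {
    rad <- sqrt(u$area[i] / pi)
    rr <- rad * sqrt(runif(n_src)); th <- runif(n_src, 0, 2 * pi)
    sx <- u$x[i] + rr * cos(th); sy <- u$y[i] + rr * sin(th)
    # keep fibre clusters inside the muscle
    out <- sqrt(sx^2 + sy^2) > anatomy$muscle_radius
    sx[out] <- u$x[i]; sy[out] <- u$y[i]
    list(v = runif(1, 3, 5),
         lambda0 = if (surface) runif(1, 5e-4, 9e-4) else runif(1, 2e-4, 4e-4),
         order = sample(1:2, 1),
         polarity = sample(c(-1, 1), 1),
         sx = sx, sy = sy,
         weight = runif(n_src, 0.5, 1.5),
         # end-plate scatter grows with territory size, dispersing (and
         # flattening) the potentials of large, late-recruited units
         jitter = rnorm(n_src, 0, 2e-4 * (1 + rad)),
         z0 = runif(1, -6, 6),         # innervation-zone offset, mm
         fibre_semilength = runif(1, 15, 25))
  }
  pars <- lapply(seq_len(n), draw_unit)

  tsamp <- (seq_len(L) - 1) / sampling_rate
  t_base <- duration_ms / 1000 * 0.3
  build_unit <- function(i, par) {
    w <- matrix(0, n_ch, L)
    # amplitude grows sub-linearly with the number of innervated fibres
    # (within-unit phase cancellation); large units still dominate the
    # interference pattern, as in real EMG
    scale <- par$polarity * u$innervation[i]^0.7 / sum(par$weight)
    # action potentials propagate in both directions from the unit's
    # innervation zone (offset z0 from the array centre) and extinguish at
    # the fibre ends, so the row profile of every unit is distinct
    zdist <- abs(pos[, "z"] - par$z0)
    taper <- 1 / (1 + exp((zdist - par$fibre_semilength) / 2))
    for (s in seq_len(n_src)) {
      d <- sqrt((par$sx[s] - pos[, "x"])^2 + (par$sy[s] - pos[, "y"])^2)
      amp <- scale * par$weight[s] * taper / (d + d0)^p
      lam <- par$lambda0 * (1 + d / 10)
      delay <- zdist / 1000 / par$v + par$jitter[s]
      for (ch in seq_len(n_ch)) {
        tt <- (tsamp - t_base - delay[ch]) / lam[ch]
        w[ch, ] <- w[ch, ] + amp[ch] * hermite_rodriguez(tt, par$order)
      }
    }
    w
  }

  tmpl <- array(0, dim = c(n, n_ch, L))
  for (i in seq_len(n)) tmpl[i, , ] <- build_unit(i, pars[[i]])

  # enforce unique multichannel profiles: redraw shape parameters of any unit
  # whose stacked template is near-proportional to another's
  flat <- matrix(tmpl, n); flat <- flat / sqrt(rowSums(flat^2))
  for (pass in 1:20) {
    cs <- abs(tcrossprod(flat)); diag(cs) <- 0
    bad <- which(apply(cs, 1, max) >= 0.99)
    if (!length(bad)) break
    for (i in bad) {
      pars[[i]] <- draw_unit(i)
      tmpl[i, , ] <- build_unit(i, pars[[i]])
      v <- as.vector(tmpl[i, , ]); flat[i, ] <- v / sqrt(sum(v^2))
    }
  }

  structure(list(templates = tmpl, duration_L = L,
                 sampling_rate = sampling_rate,
                 conduction_velocity = vapply(pars, `[[`, 1, "v"),
                 array = array, positions = pos, anatomy = anatomy),
            class = "muap_templates")
}

# Hermite-Rodriguez waveforms: order 1 biphasic, order 2 triphasic
hermite_rodriguez <- function(t, order = 1) {
  if (order == 1) t * exp(-t^2) else (1 - 2 * t^2) * exp(-t^2)
}

#' @export
print.muap_templates <- function(x, ...) {
  cat(sprintf("<muap_templates> %d units x %d channels x %d samples (%s, %g Hz)\n",
              dim(x$templates)[1], dim(x$templates)[2], x$duration_L,
              x$array$kind, x$sampling_rate))
  invisible(x)
}

#' Per-unit spatial support of templates
#'
#' Number of channels whose peak-to-peak template amplitude exceeds
#' `frac` of the unit's maximum peak-to-peak amplitude.
#'
#' @param templates a `muap_templates`.
#' @param frac fraction of the per-unit maximum (default 0.1).
#' @return integer vector, one entry per unit.
#' @export
template_support <- function(templates, frac = 0.1) {
  tt <- templates$templates
  apply(tt, 1, function(w) {
    p2p <- apply(w, 1, function(ch) diff(range(ch)))
    sum(p2p > frac * max(p2p))
  })
}
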