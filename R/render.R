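#' Render multichannel EMG from ground truth and templates
#'
#' Each channel is the sum over units of the convolution between the unit's
#' discharge delta train and its channel template, plus white Gaussian noise
#' scaled so that the whole-record signal-to-noise ratio equals `snr_db`
#' (`snr_db = Inf` disables noise).
#'
#' @param truth a [simulate_contraction()] result.
#' @param templates a [synthesize_muap_templates()] set covering all units.
#' @param snr_db signal-to-noise ratio over the record, dB; default 20
#'   (surface) or 30 (intramuscular) from [mu_config()].
#' @param seed integer seed for the noise realisation.
#' @param config a [mu_config()].
#' @return An `emg_recording` (channels x samples matrix plus sampling rate,
#'   array geometry and an all-`TRUE` channel mask).
#' @export
render_emg <- function(truth, templates, snr_db = NULL, seed = NULL,
                       config = mu_config()) {
  stopifnot(inherits(truth, "sim_truth"), inherits(templates, "muap_templates"))
  if (truth$sampling_rate != templates$sampling_rate)
    abort("truth and templates have different sampling rates",
          class = "mudecomp_invalid_argument")
  if (truth$n_units != dim(templates$templates)[1])
    abort("templates do not cover all units in truth",
          class = "mudecomp_invalid_argument")
  snr_db <- snr_db %||% if (templates$array$kind == "surface_grid")
    config$simulator$snr_db_surface else config$simulator$snr_db_intramuscular
  if (is.na(snr_db) || is.nan(snr_db))
    abort("snr_db must be finite or Inf", class = "mudecomp_invalid_argument")
  if (!is.null(seed)) set.seed(seed)

  tt <- templates$templates
  n_ch <- dim(tt)[2]; L <- dim(tt)[3]
  T_len <- length(truth$force)
  X <- matrix(0, n_ch, T_len + L)
  for (i in seq_len(truth$n_units)) {
    sp <- truth$spike_trains[[i]]
    if (!length(sp)) next
    w <- tt[i, , , drop = TRUE]
    if (is.null(dim(w))) w <- matrix(w, 1)   # single-channel array
    for (l in seq_len(L)) {
      cols <- sp + l - 1L                    # distinct for fixed l
      X[, cols] <- X[, cols] + w[, l]
    }
  }
  X <- X[, seq_len(T_len), drop = FALSE]

  if (is.finite(snr_db)) {
    p_sig <- mean(X^2)
    sigma <- sqrt(p_sig / 10^(snr_db / 10))
    X <- X + matrix(rnorm(length(X), sd = sigma), nrow = n_ch)
  }
  new_emg_recording(X, truth$sampling_rate, templates$array,
                    meta = list(snr_db = snr_db, seed = seed))
}

#' Simulate a full recording in one call
#'
#' Convenience wrapper chaining [simulate_contraction()],
#' [synthesize_muap_templates()] (unless given) and [render_emg()].
#'
#' @inheritParams render_emg
#' @inheritParams simulate_contraction
#' @param array an [electrode_array()] (used when `templates` is `NULL`).
#' @param anatomy a [muscle_anatomy()].
#' @param templates optional pre-built template set, so several contractions
#'   can share the same units and action potentials.
#' @param seed integer; sub-seeds are derived for the contraction, the
#'   templates and the noise.
#' @return list with `recording`, `truth`, `templates`.
#' @export
simulate_recording <- function(pool, profile, array = electrode_array("surface_grid"),
                               anatomy = muscle_anatomy(), templates = NULL,
                               snr_db = NULL, seed = 1, config = mu_config()) {
  if (is.null(templates))
    templates <- synthesize_muap_templates(pool, anatomy, array,
                                           profile$sampling_rate, seed = seed * 7L + 1L)
  truth <- simulate_contraction(pool, profile, seed = seed * 7L + 2L, config = config)
  rec <- render_emg(truth, templates, snr_db = snr_db, seed = seed * 7L + 3L,
                    config = config)
  list(recording = rec, truth = truth, templates = templates)
}
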