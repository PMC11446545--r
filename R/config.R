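#' Default run configuration
#'
#' Collects every tunable parameter of the pipeline in one nested list:
#' simulator (anatomy, pool, controller gains, noise levels), decomposition
#' (extension rule, contrast, convergence, silhouette gate, duplicate rule),
#' real-time (epoch length, rate windows) and metrics (matching tolerance,
#' lag search) settings. Values can be overridden per section, e.g.
#' `mu_config(decomposition = list(n_sources = 20))`.
#'
#' @param ... named sections (`simulator`, `decomposition`, `realtime`,
#'   `metrics`, `editing`) whose entries override the defaults.
#' @return A nested named list with class `mu_config`.
#' @examples
#' cfg <- mu_config(decomposition = list(n_sources = 10))
#' cfg$decomposition$sil_threshold
#' @export
mu_config <- function(...) {
  defaults <- list(
    simulator = list(
      n_units = 150,
      snr_db_surface = 20,
      snr_db_intramuscular = 30,
      # PID gains on the force error (% MVC), tuned once for <= 1% MVC
      # plateau tracking error and kept fixed thereafter
      pid = list(kp = 1e-2, ki = 5e-2, kd = 0),
      drive_max = 1.5,
      duration = 30,
      ramp_duration = 5,
      plateau_duration = 20
    ),
    decomposition = list(
      extension_target = 1000,   # R = round(extension_target / m), floor 1
      contrast = "square",
      tol = 1e-4,
      max_iter = 100,
      n_sources = 50,
      sil_threshold = 0.90,
      max_cov_isi = 0.35,      # steady isometric discharge is regular
      min_spikes = 10,
      min_separation_ms = 25,
      max_refine_iter = 20,
      duplicate_share = 0.30,
      duplicate_tol_ms = 0.5,
      duplicate_lag_ms = 50    # covers the delayed-replica ambiguity (R + L)
    ),
    realtime = list(
      epoch_ms = 125,
      rate_window_epochs = 8,
      rate_smooth_values = 4
    ),
    metrics = list(
      tolerance_ms = 0.5,
      max_lag_ms = 10
    ),
    editing = list(
      rate_max_pps = 50,
      rate_min_pps = 2,
      sil_threshold = 0.90
    )
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) abort(paste0("unknown config section(s): ",
                                paste(bad, collapse = ", ")),
                         class = "mudecomp_invalid_argument")
  for (s in names(over)) defaults[[s]] <- utils::modifyList(defaults[[s]], over[[s]])
  structure(defaults, class = "mu_config")
}
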