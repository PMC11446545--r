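#' Deterministic test fixtures
#'
#' Small synthetic datasets generated in code (no files), used throughout the
#' test suite:
#'
#' * `toy_two_units` — two motor units with disjoint multichannel templates
#'   (each unit projects onto its own group of channels) mixed without noise
#'   over 4 s of 8-channel signal at 2048 Hz; offline decomposition recovers
#'   both trains exactly.
#' * `toy_noise_only` — 3 s of pure white Gaussian noise on 8 channels; the
#'   silhouette gate accepts nothing.
#' * `mini_protocol` — a reduced pool protocol (20 units, 8 x 4 surface grid,
#'   2 s ramps + 10 s plateau at 20% MVC, 20 dB) that runs end-to-end in
#'   well under a minute.
#'
#' @param kind fixture name.
#' @param seed integer seed.
#' @return list with `recording`, `truth` (where applicable), `templates`,
#'   `pool` (mini protocol).
#' @export
make_fixture <- function(kind = c("toy_two_units", "toy_noise_only",
                                  "mini_protocol"), seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "toy_two_units") {
    fs <- 2048; T_len <- 4 * fs; n_ch <- 8
    L <- 20
    tmpl <- array(0, dim = c(2, n_ch, L))
    base1 <- hermite_rodriguez((seq_len(L) - 6) / 3, 1)
    base2 <- hermite_rodriguez((seq_len(L) - 10) / 4, 2)
    for (ch in 1:4) tmpl[1, ch, ] <- base1 * (1.4 - 0.2 * ch)
    for (ch in 5:8) tmpl[2, ch, ] <- base2 * (0.4 + 0.15 * ch)
    mk_train <- function(rate, n) {
      isi <- (fs / rate) * (1 + 0.1 * pmax(pmin(rnorm(n), 3), -3))
      sp <- as.integer(round(cumsum(isi))) + 200L
      sp[sp < T_len - L]
    }
    truth <- structure(list(
      spike_trains = list(unit_1 = mk_train(13, 60), unit_2 = mk_train(9, 45)),
      force = numeric(T_len), drive = numeric(T_len),
      target = numeric(T_len), sampling_rate = fs, n_units = 2L, seed = seed
    ), class = "sim_truth")
    templates <- structure(list(
      templates = tmpl, duration_L = L, sampling_rate = fs,
      conduction_velocity = c(4, 4),
      array = electrode_array("surface_grid", n_rows = 8, n_cols = 1,
                              inter_electrode_distance = 4,
                              sampling_rate = fs),
      positions = NULL, anatomy = muscle_anatomy()
    ), class = "muap_templates")
    rec <- render_emg(truth, templates, snr_db = Inf)
    list(recording = rec, truth = truth, templates = templates)
  } else if (kind == "toy_noise_only") {
    fs <- 2048
    rec <- new_emg_recording(matrix(rnorm(8 * 3 * fs), nrow = 8), fs)
    list(recording = rec)
  } else {
    fs <- 2048
    pool <- build_motor_unit_pool(20, seed = seed)
    array <- electrode_array("surface_grid", n_rows = 8, n_cols = 4,
                             inter_electrode_distance = 4, sampling_rate = fs)
    profile <- generate_force_profile("trapezoid", sampling_rate = fs,
                                      ramp_duration = 2, plateau_duration = 10,
                                      plateau_level = 20)
    sim <- simulate_recording(pool, profile, array, seed = seed)
    c(sim, list(pool = pool))
  }
}
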