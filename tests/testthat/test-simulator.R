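test_that("pool invariants: innervation range, territories inside the muscle, ordered thresholds", {
  pool <- build_motor_unit_pool(150, seed = 1)
  u <- pool$units
  expect_gte(min(u$innervation), 66)
  expect_lte(max(u$innervation), 3321)
  expect_true(all(u$area >= 0.8 & u$area <= 78.5))
  expect_true(all(sqrt(u$x^2 + u$y^2) <= pool$anatomy$muscle_radius))
  expect_true(all(diff(u$threshold) > 0))
  expect_true(all(u$twitch_contraction_time >= 0.03 - 1e-12 &
                  u$twitch_contraction_time <= 0.1 + 1e-12))

  single <- build_motor_unit_pool(1, seed = 2)
  expect_lte(sqrt(single$units$x^2 + single$units$y^2), 10)

  expect_error(build_motor_unit_pool(0), class = "mudecomp_invalid_argument")
  expect_identical(build_motor_unit_pool(30, seed = 5),
                   build_motor_unit_pool(30, seed = 5))
})

test_that("innervation numbers follow the truncated exponential", {
  pool_a <- build_motor_unit_pool(150, seed = 1)
  pool_b <- build_motor_unit_pool(150, seed = 2)
  ks_pools <- suppressWarnings(
    stats::ks.test(pool_a$units$innervation, pool_b$units$innervation))
  expect_gt(ks_pools$statistic, 0)          # different seeds, different draws
  expect_lt(ks_pools$statistic, 0.16)       # ... from the same distribution
  # oracle: direct inverse-CDF draws from the same truncated exponential
  set.seed(99)
  scale <- (3321 - 66) / log(3321 / 66)
  direct <- 66 - scale * log(1 - runif(4000) * (1 - exp(-(3321 - 66) / scale)))
  ks_direct <- suppressWarnings(
    stats::ks.test(pool_a$units$innervation, direct))
  expect_lt(ks_direct$statistic, 0.12)
})

test_that("force profiles: sinusoid range and trapezoid geometry", {
  fs <- 2048
  sine <- generate_force_profile("sinusoid", fs, sine_centre = 20,
                                 sine_amplitude = 5, sine_frequency = 0.5)
  expect_equal(min(sine$target), 15)
  expect_equal(max(sine$target), 25)

  trap <- generate_force_profile("trapezoid", fs, ramp_duration = 5,
                                 plateau_duration = 20, plateau_level = 30)
  expect_length(trap$target, (5 + 20 + 5) * fs)
  expect_equal(trap$target[round(2.5 * fs)], 15)   # mid-ramp
  expect_equal(max(trap$target), 30)

  flat <- generate_force_profile("trapezoid", fs, ramp_duration = 0,
                                 plateau_duration = 2, plateau_level = 20)
  expect_true(all(flat$target == 20))

  expect_error(generate_force_profile("trapezoid", fs, ramp_duration = -1),
               class = "mudecomp_invalid_argument")
})

test_that("closed-loop contraction tracks the plateau and recruits by threshold", {
  pool <- build_motor_unit_pool(150, seed = 1)
  fs <- 2048
  active <- function(tr) which(vapply(tr$spike_trains, length, 1L) > 0)
  t20 <- simulate_contraction(pool, generate_force_profile("trapezoid", fs, 2.5, 10, 20), seed = 3)
  expect_lt(plateau_tracking_error(t20), 1)

  # zero target recruits nothing
  t0 <- simulate_contraction(pool, generate_force_profile("trapezoid", fs, 0.5, 1, 0), seed = 3)
  expect_equal(sum(vapply(t0$spike_trains, length, 1L)), 0)

  # threshold-ordered recruitment: active units at 10% are a subset of 30%
  t10 <- simulate_contraction(pool, generate_force_profile("trapezoid", fs, 2.5, 10, 10), seed = 4)
  t30 <- simulate_contraction(pool, generate_force_profile("trapezoid", fs, 2.5, 10, 30), seed = 5)
  expect_true(all(active(t10) %in% active(t30)))
  expect_gt(length(active(t30)), length(active(t10)))
  # spike trains strictly increasing
  for (sp in t20$spike_trains) if (length(sp) > 1) expect_true(all(diff(sp) > 0))

  expect_identical(
    simulate_contraction(pool, generate_force_profile("trapezoid", fs, 1, 2, 20), seed = 7),
    simulate_contraction(pool, generate_force_profile("trapezoid", fs, 1, 2, 20), seed = 7))
})

test_that("ISI coefficient of variation matches the configured jitter on constant drive", {
  pool <- build_motor_unit_pool(30, seed = 2)
  fs <- 2048
  prof <- generate_force_profile("trapezoid", fs, 0.1, 19.8, 20)
  ol <- simulate_contraction(pool, prof, drive = rep(0.3, length(prof$target)), seed = 6)
  long <- vapply(ol$spike_trains, length, 1L) > 60
  cv <- vapply(ol$spike_trains[long], function(s) {
    isi <- diff(s[s > fs])                  # skip the first second
    sd(isi) / mean(isi)
  }, 0)
  expect_true(all(cv > 0.15 * 0.7 & cv < 0.15 * 1.3))
})

test_that("open-loop force equals the analytic twitch superposition", {
  pool <- build_motor_unit_pool(5, seed = 3, isi_cov = 0)
  fs <- 2048
  prof <- generate_force_profile("trapezoid", fs, 0.1, 3.8, 20)
  drive <- rep(0.5, length(prof$target))
  tr <- simulate_contraction(pool, prof, drive = drive, seed = 1)
  # oracle: direct convolution of the delta trains with the sampled twitch
  u <- pool$units
  fmax <- mudecomp:::pool_max_force(pool)
  T_len <- length(prof$target)
  force <- numeric(T_len)
  for (i in seq_len(pool$n_units)) {
    tc <- u$twitch_contraction_time[i]
    nk <- ceiling(6 * tc * fs)
    kern <- u$twitch_amplitude[i] * ((1:nk) / fs / tc) * exp(1 - (1:nk) / fs / tc)
    for (s in tr$spike_trains[[i]]) {
      idx <- s + seq_len(nk)
      ok <- idx <= T_len
      force[idx[ok]] <- force[idx[ok]] + kern[ok]
    }
  }
  expect_equal(tr$force, 100 * force / fmax, tolerance = 1e-10)
})

test_that("unstable gains raise a divergence error", {
  pool <- build_motor_unit_pool(50, seed = 4)
  prof <- generate_force_profile("trapezoid", 2048, 1, 5, 30)
  expect_error(
    simulate_contraction(pool, prof, gains = list(kp = 50, ki = 500, kd = 0),
                         seed = 1,
                         config = mu_config(simulator = list(drive_max = 100))),
    class = "mudecomp_simulation_diverged")
})

test_that("templates decay with distance and intramuscular support is narrower", {
  pool <- build_motor_unit_pool(40, seed = 5)
  surf <- synthesize_muap_templates(pool, array = electrode_array("surface_grid"),
                                    seed = 6)
  intra <- synthesize_muap_templates(pool, array = electrode_array("intramuscular_array"),
                                     seed = 6)
  expect_gt(median(template_support(surf)), median(template_support(intra)))

  # monotone decay: near channel beats a 10 mm farther one for every unit
  pos <- surf$positions
  u <- pool$units
  for (i in c(1, 20, 40)) {
    d <- sqrt((u$x[i] - pos[, "x"])^2 + (u$y[i] - pos[, "y"])^2)
    p2p <- apply(surf$templates[i, , ], 1, function(ch) diff(range(ch)))
    far <- which(d > d[which.min(d)] + 8)
    if (length(far)) expect_gt(p2p[which.min(d)], max(p2p[far]))
  }

  # no two units share a proportional multichannel template
  flat <- matrix(surf$templates, nrow = 40)
  flat <- flat / sqrt(rowSums(flat^2))
  cs <- abs(tcrossprod(flat)); diag(cs) <- 0
  expect_lt(max(cs), 0.99)
})

test_that("rendering is the convolution of delta trains with templates plus scaled noise", {
  fx <- make_fixture("toy_two_units", seed = 1)
  # single spike, zero noise: the output equals the template at that offset
  truth1 <- fx$truth
  truth1$spike_trains <- list(unit_1 = 500L, unit_2 = integer(0))
  rec1 <- render_emg(truth1, fx$templates, snr_db = Inf)
  L <- fx$templates$duration_L
  expect_equal(rec1$data[, 500:(500 + L - 1)], fx$templates$templates[1, , ])
  expect_true(all(rec1$data[, 1:499] == 0))

  # SNR definition: noise variance = signal variance / 10^(snr/10)
  clean <- render_emg(fx$truth, fx$templates, snr_db = Inf)
  noisy <- render_emg(fx$truth, fx$templates, snr_db = 20, seed = 3)
  noise <- noisy$data - clean$data
  expect_equal(mean(noise^2), mean(clean$data^2) / 100, tolerance = 0.05)

  expect_error(render_emg(fx$truth, fx$templates, snr_db = NaN),
               class = "mudecomp_invalid_argument")

  # conservation: rendered onsets per unit equal the ground-truth train length
  expect_identical(
    render_emg(fx$truth, fx$templates, snr_db = Inf, seed = 5),
    render_emg(fx$truth, fx$templates, snr_db = Inf, seed = 5))
})
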