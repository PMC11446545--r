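# Shared fixtures, built once per test run and memoised. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

toy_two_units <- function() cached("toy2", function() make_fixture("toy_two_units", seed = 1))
toy_noise <- function() cached("toynoise", function() make_fixture("toy_noise_only", seed = 2))
mini_protocol <- function() cached("mini", function() make_fixture("mini_protocol", seed = 1))

# offline decomposition of the toy mixture (cheap, exact-recovery fixture)
toy_decomp <- function() cached("toy2_dec", function() {
  decompose_offline(toy_two_units()$recording,
                    mu_config(decomposition = list(n_sources = 4)), seed = 1)
})

# offline decomposition of the mini protocol (the workhorse for realtime /
# editing / recalibration tests)
mini_decomp <- function() cached("mini_dec", function() {
  decompose_offline(mini_protocol()$recording,
                    mu_config(decomposition = list(n_sources = 10)), seed = 1)
})

# whitened reference signal of the mini protocol, for edit sessions
mini_whitened <- function() cached("mini_xw", function() {
  decomp <- mini_decomp()
  rec <- apply_mask(mini_protocol()$recording)
  whiten_emg(extend_emg(rec, decomp$calibration$R))
})

# a corrupted version of a known-good train: double-detection false positives
# (5-12 ms after true discharges) plus random deletions
corrupt_train <- function(train, fs, n_fp, n_del, seed = 1) {
  set.seed(seed)
  fp <- sort(sample(train, n_fp)) + round(runif(n_fp, 0.005, 0.012) * fs)
  keep <- sort(sample(seq_along(train), length(train) - n_del))
  list(train = sort(unique(c(train[keep], fp))), fp = fp,
       deleted = train[-keep])
}

# corruption with realistic false-positive modes: double detections (caught
# by the rate bounds) plus misclassified noise peaks of the unit's own pulse
# train (caught by the silhouette-gated recompute), plus deletions
corrupt_train_realistic <- function(xw, train, frac = 0.02, seed = 1) {
  fs <- xw$sampling_rate
  n_bad <- max(2, round(frac * length(train)))
  d <- mudecomp:::session_derive(xw, train, 25)
  noise_pk <- d$pt$peaks$sample[d$pt$peaks$class == "noise"]
  sep <- round(0.025 * fs)
  noise_pk <- noise_pk[vapply(noise_pk, function(s) min(abs(train - s)) > sep, NA)]
  set.seed(seed)
  fp_dd <- sort(sample(train, n_bad)) + round(runif(n_bad, 0.005, 0.012) * fs)
  fp_np <- sort(sample(noise_pk, n_bad))
  keep <- sort(sample(seq_along(train), length(train) - n_bad))
  list(train = sort(unique(c(train[keep], fp_dd, fp_np))),
       fp = c(fp_dd, fp_np), deleted = train[-keep])
}
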