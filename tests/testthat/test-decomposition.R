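test_that("toy two-unit mixture is recovered exactly", {
  fx <- toy_two_units()
  dec <- toy_decomp()
  expect_equal(length(dec$filters), 2)
  sc <- score_against_truth(dec, fx$truth)
  expect_setequal(sc$truth_unit, 1:2)
  expect_equal(sc$roa, c(1, 1))
  expect_equal(sc$fp + sc$fn, c(0, 0))
})

test_that("separation vectors stay unit-norm and deflation-orthogonal", {
  fx <- toy_two_units()
  xw <- whiten_emg(extend_emg(apply_mask(fx$recording)))
  e1 <- extract_source(xw, max_iter = 50)
  expect_equal(sqrt(sum(e1$w^2)), 1, tolerance = 1e-9)
  e2 <- extract_source(xw, prior_filters = cbind(e1$w), max_iter = 50)
  expect_equal(sqrt(sum(e2$w^2)), 1, tolerance = 1e-9)
  expect_lt(abs(sum(e1$w * e2$w)), 1e-9)
  e3 <- extract_source(xw, prior_filters = cbind(e1$w, e2$w), max_iter = 50)
  G <- crossprod(cbind(e1$w, e2$w, e3$w))
  expect_lt(max(abs(G - diag(3))), 1e-9)
})

test_that("accepted filters of a full decomposition satisfy the gate and norm contracts", {
  dec <- mini_decomp()
  expect_gt(length(dec$filters), 0)
  for (f in dec$filters) {
    expect_equal(sqrt(sum(f$w^2)), 1, tolerance = 1e-9)
    expect_gte(f$sil, dec$config$decomposition$sil_threshold)
    expect_gt(f$spike_centroid, f$noise_centroid)
  }
  low <- dec$rejected[dec$rejected$reason == "low-SIL", ]
  if (nrow(low)) expect_true(all(low$sil < dec$config$decomposition$sil_threshold))
  # deflation basis of the candidates is orthonormal
  B <- vapply(dec$filters, `[[`, numeric(length(dec$filters[[1]]$w_deflation)),
              "w_deflation")
  G <- crossprod(B)
  expect_lt(max(abs(G - diag(ncol(B)))), 1e-6)
  # one spike train per accepted filter, strictly increasing
  expect_equal(length(dec$spike_trains), length(dec$filters))
  for (sp in dec$spike_trains) expect_true(all(diff(sp) > 0))
})

test_that("pure noise yields zero accepted filters", {
  dec <- decompose_offline(toy_noise()$recording,
                           mu_config(decomposition = list(n_sources = 5)),
                           seed = 1)
  expect_equal(length(dec$filters), 0)
})

test_that("decomposition is deterministic given the seed", {
  fx <- toy_two_units()
  cfg <- mu_config(decomposition = list(n_sources = 3))
  d1 <- decompose_offline(fx$recording, cfg, seed = 42)
  d2 <- decompose_offline(fx$recording, cfg, seed = 42)
  expect_identical(d1$filters, d2$filters)
  expect_identical(d1$spike_trains, d2$spike_trains)
})

test_that("CoV refinement never increases the CoV of the interspike intervals", {
  fx <- toy_two_units()
  xw <- whiten_emg(extend_emg(apply_mask(fx$recording)))
  es <- extract_source(xw, max_iter = 60)
  pt <- detect_and_classify_peaks(es$source^2, 2048)
  cv0 <- mudecomp:::cov_isi(pt$peaks$sample[pt$peaks$class == "spike"])
  ref <- refine_by_cov_isi(es$w, xw, pt)
  expect_lte(ref$cov_isi, cv0 + 1e-12)

  # a perfectly regular train has CoV 0 and survives one confirmation pass
  w_true <- mudecomp:::sta_filter(xw$whitened, seq(500, 7000, by = 130))
  expect_equal(mudecomp:::cov_isi(seq(500, 7000, by = 130)), 0)
})

test_that("refinement recovers a missed spike injected into a good train", {
  fx <- toy_two_units()
  dec <- toy_decomp()
  xw <- whiten_emg(extend_emg(apply_mask(fx$recording), dec$calibration$R))
  train <- dec$spike_trains[[1]]
  corrupt <- train[-3]                       # drop one discharge
  w0 <- mudecomp:::sta_filter(xw$whitened, corrupt)
  pt0 <- detect_and_classify_peaks(as.vector(crossprod(w0, xw$whitened))^2, 2048)
  ref <- refine_by_cov_isi(w0, xw, pt0)
  expect_true(train[3] %in% ref$spikes)
  expect_setequal(ref$spikes, train)
})

test_that("duplicate removal keeps the higher-silhouette member", {
  dec <- toy_decomp()
  # construct a decomposition with an artificial duplicate (shifted copy)
  dup <- dec
  f3 <- dup$filters[[1]]
  f3$sil <- f3$sil - 0.01
  f3$source_id <- 99L
  dup$filters[[3]] <- f3
  dup$spike_trains[[3]] <- dup$spike_trains[[1]] + 3L   # lag 3 samples, 100% shared
  pruned <- remove_duplicates(dup, share_threshold = 0.3, tol_ms = 0.5, lag_ms = 10)
  expect_equal(length(pruned$filters), 2)
  expect_true(99L %in% pruned$rejected$source_id)

  # disjoint trains are untouched
  expect_equal(length(remove_duplicates(dec)$filters), length(dec$filters))

  # 50% sharing at a 3-sample lag is flagged
  half <- dec
  tr <- half$spike_trains[[1]]
  mixed <- sort(c(tr[seq(1, length(tr), by = 2)] + 3L,
                  seq(200, 6000, by = 400)))
  f9 <- half$filters[[1]]; f9$sil <- f9$sil - 0.02; f9$source_id <- 98L
  half$filters[[3]] <- f9
  half$spike_trains[[3]] <- mixed
  pruned2 <- remove_duplicates(half, share_threshold = 0.3)
  expect_true(98L %in% pruned2$rejected$source_id)
})

test_that("tidiers summarise a decomposition", {
  dec <- toy_decomp()
  td <- tidy(dec)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), length(dec$filters))
  expect_true(all(c("unit", "sil", "cov_isi", "n_spikes") %in% names(td)))
  g <- glance(dec)
  expect_equal(g$n_accepted, length(dec$filters))
})
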