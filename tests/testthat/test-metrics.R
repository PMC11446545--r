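fs <- 2048

test_that("matching identities on identical and pruned trains", {
  ref <- sort(sample(1000:20000, 50))
  m <- match_spike_trains(ref, ref, fs)
  expect_equal(c(m$tp, m$fp, m$fn), c(50, 0, 0))

  test <- ref[-c(3, 17)]
  m2 <- match_spike_trains(test, ref, fs)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(48, 0, 2))
  expect_equal(m2$tp + m2$fn, length(ref))
  expect_equal(m2$tp + m2$fp, length(test))
})

test_that("constant-lag alignment recovers a shifted train", {
  set.seed(8)
  ref <- sort(sample(seq(500, 40000, by = 60), 80))
  shift <- round(0.002 * fs)                 # 2 ms
  m <- match_spike_trains(ref + shift, ref, fs, tolerance_ms = 0.5, align = TRUE)
  expect_equal(m$tp, length(ref))
  # within the tolerance several lags tie; the tie-break takes the smallest
  tol <- round(0.5 / 1000 * fs)
  expect_lte(abs(m$lag_applied + shift), tol)
  # without alignment the same shift matches nothing at +/- 0.5 ms
  m0 <- match_spike_trains(ref + shift, ref, fs, align = FALSE)
  expect_equal(m0$tp, 0)
  # oracle: exhaustive lag search maximising coincidences
  tol <- round(0.5 / 1000 * fs)
  cnt <- vapply(-25:25, function(l)
    sum(abs(outer(ref, ref + shift + l, "-")) <= tol), 0L)
  expect_equal(max(cnt), m$tp)
})

test_that("matching is injective (agrees with brute-force optimal matching on small trains)", {
  # brute-force maximum bipartite matching by permutation enumeration
  brute_tp <- function(test, ref, tol) {
    best <- 0
    k <- length(test)
    for (perm in combinat_perms(seq_len(k))) {
      tp <- 0
      used <- logical(length(ref))
      for (j in perm) {
        ok <- which(!used & abs(ref - test[j]) <= tol)
        if (length(ok)) { used[ok[1]] <- TRUE; tp <- tp + 1 }
      }
      best <- max(best, tp)
    }
    best
  }
  combinat_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(combinat_perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  set.seed(9)
  for (case in 1:10) {
    ref <- sort(sample(1:120, 5))
    test <- sort(pmax(1, ref[sample(5, 4)] + sample(-2:2, 4, replace = TRUE)))
    m <- match_spike_trains(test, ref, fs = 1000, tolerance_ms = 2000, align = FALSE)
    expect_lte(m$tp, min(length(test), length(ref)))
    expect_equal(m$tp, brute_tp(test, ref, tol = 2))
  }
})

test_that("agreement scores follow the printed formulas", {
  m <- structure(list(tp = 8, fp = 0, fn = 2), class = "mu_match")
  sc <- agreement_scores(m)
  expect_equal(unlist(sc), c(roa = 0.8, sensitivity = 0.8, precision = 1, fnr = 0.2))

  m2 <- structure(list(tp = 90, fp = 5, fn = 5), class = "mu_match")
  sc2 <- agreement_scores(m2)
  expect_equal(sc2$roa, 0.9)
  expect_equal(sc2$sensitivity, 90 / 95)
  expect_equal(sc2$precision, 90 / 95)

  m3 <- structure(list(tp = 0, fp = 3, fn = 4), class = "mu_match")
  expect_equal(agreement_scores(m3)$roa, 0)

  m4 <- structure(list(tp = 0, fp = 0, fn = 4), class = "mu_match")
  expect_error(agreement_scores(m4), class = "mudecomp_undefined_scores")
})

test_that("score identities: sens + fnr = 1 and RoA <= min(sens, prec)", {
  set.seed(10)
  for (i in 1:20) {
    ref <- sort(sample(1000:30000, sample(20:60, 1)))
    test <- sort(unique(c(ref[runif(length(ref)) < 0.8],
                          sample(1000:30000, 5))))
    m <- match_spike_trains(test, ref, fs)
    sc <- agreement_scores(m)
    expect_equal(sc$sensitivity + sc$fnr, 1)
    expect_lte(sc$roa, min(sc$sensitivity, sc$precision) + 1e-12)
  }
})

test_that("swapping test and reference swaps sensitivity and precision, RoA unchanged", {
  set.seed(11)
  ref <- sort(sample(seq(1000, 50000, by = 80), 60))
  test <- sort(c(ref[-c(2, 9, 30)], c(1500, 2500, 3500, 4500) + 7))
  a <- agreement_scores(match_spike_trains(test, ref, fs, align = FALSE))
  b <- agreement_scores(match_spike_trains(ref, test, fs, align = FALSE))
  expect_equal(a$roa, b$roa)
  expect_equal(a$sensitivity, b$precision)
  expect_equal(a$precision, b$sensitivity)
})

test_that("mismatched sampling rates are an invalid comparison", {
  expect_error(match_spike_trains(1:3, 1:3, fs = 2048, fs_ref = 10240),
               class = "mudecomp_invalid_comparison")
})

test_that("rate RMSE identities and the glitch oracle", {
  x <- c(rep(8, 50), rep(10, 50))
  expect_equal(rate_rmse(x, x), 0)
  expect_equal(rate_rmse(x + 1, x), 1)
  y <- rep(8, 100); z <- y; z[40] <- 12     # one 4-pps glitch in 1 of 100 windows
  expect_equal(rate_rmse(z, y), sqrt(16 / 100))
  expect_equal(rate_rmse(z, y), 0.4)
  expect_error(rate_rmse(1:3, 1:4), class = "mudecomp_invalid_comparison")
})

test_that("smoothed rates implement the 8-epoch sum and 4-value mean", {
  esamp <- round(0.125 * fs)
  # one spike per epoch for 16 epochs
  spikes <- (0:15) * esamp + 10
  sr <- smoothed_rates(spikes, n_samples = 16 * esamp, fs = fs)
  expect_equal(sr$rate_raw[8:16], rep(8, 9))   # 8 spikes in the trailing second
  expect_equal(sr$rate_raw[1], 1)
  # raw rate x 1 s is always an integer spike count
  expect_true(all(sr$rate_raw == round(sr$rate_raw)))
  # mean of last 4 raw values
  expect_equal(sr$rate_smooth[16], mean(sr$rate_raw[13:16]))
})
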