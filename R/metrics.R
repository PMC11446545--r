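#' Match two spike trains
#'
#' Optionally removes a constant lag (the lag in `-max_lag_ms..max_lag_ms`
#' that maximises the number of coincidences within the tolerance, i.e. the
#' peak of the binary-train cross-correlation smoothed over the tolerance
#' window), then performs greedy one-to-one matching: reference discharges
#' are visited in time order and each claims the nearest unmatched test
#' discharge within the tolerance (ties toward the earlier test discharge).
#'
#' @param test,ref spike trains as strictly increasing integer sample
#'   indices.
#' @param fs sampling rate of both trains, Hz.
#' @param tolerance_ms matching tolerance (default +/- 0.5 ms).
#' @param align search for and remove a constant lag first.
#' @param max_lag_ms lag search range, ms.
#' @param fs_ref sampling rate of `ref` if different (an error: trains must
#'   share a sampling rate).
#' @return A `mu_match`: `tp`, `fp`, `fn`, `lag_applied` (samples, added to
#'   test times before matching), `tolerance_ms`, plus the matched index
#'   pairs and the unmatched (false-positive) test samples.
#' @export
match_spike_trains <- function(test, ref, fs, tolerance_ms = 0.5,
                               align = TRUE, max_lag_ms = 10, fs_ref = fs) {
  if (fs_ref != fs)
    abort("test and reference trains have different sampling rates",
          class = "mudecomp_invalid_comparison")
  test <- as.numeric(sort(test)); ref <- as.numeric(sort(ref))
  tol <- max(0L, round(tolerance_ms / 1000 * fs))
  lag <- 0L
  if (align && length(test) && length(ref)) {
    max_lag <- round(max_lag_ms / 1000 * fs)
    d <- as.vector(outer(ref, test, "-"))
    d <- d[abs(d) <= max_lag + tol]
    if (length(d)) {
      lags <- -max_lag:max_lag
      cnt <- vapply(lags, function(l) sum(abs(d - l) <= tol), 0L)
      best <- which(cnt == max(cnt))
      lag <- lags[best[order(abs(lags[best]), lags[best])[1]]]
    }
  }
  shifted <- test + lag
  used <- logical(length(shifted))
  match_ref <- integer(0); match_test <- integer(0)
  j_lo <- 1L
  for (i in seq_along(ref)) {
    r <- ref[i]
    while (j_lo <= length(shifted) && shifted[j_lo] < r - tol) j_lo <- j_lo + 1L
    j <- j_lo; best_j <- 0L; best_d <- Inf
    while (j <= length(shifted) && shifted[j] <= r + tol) {
      if (!used[j]) {
        dj <- abs(shifted[j] - r)
        if (dj < best_d) { best_d <- dj; best_j <- j }  # tie -> earlier test
      }
      j <- j + 1L
    }
    if (best_j > 0L) {
      used[best_j] <- TRUE
      match_ref <- c(match_ref, i); match_test <- c(match_test, best_j)
    }
  }
  tp <- length(match_ref)
  structure(list(tp = tp, fp = length(test) - tp, fn = length(ref) - tp,
                 lag_applied = lag, tolerance_ms = tolerance_ms,
                 n_test = length(test), n_ref = length(ref),
                 matched_ref = match_ref, matched_test = match_test,
                 fp_samples = test[!used]),
            class = "mu_match")
}

#' @export
print.mu_match <- function(x, ...) {
  cat(sprintf("<mu_match> tp %d, fp %d, fn %d (lag %d samples, tol %.2g ms)\n",
              x$tp, x$fp, x$fn, x$lag_applied, x$tolerance_ms))
  invisible(x)
}

#' @describeIn match_spike_trains counts as a one-row tibble.
#' @param x a `mu_match`.
#' @param ... unused.
#' @export
tidy.mu_match <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn,
                 lag_applied = x$lag_applied, tolerance_ms = x$tolerance_ms)
}

#' Agreement scores between spike trains
#'
#' `sensitivity = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `fnr = FN / (TP + FN)`, and the rate of agreement
#' `roa = TP / (TP + FN + FP)`.
#'
#' @param m a [match_spike_trains()] result.
#' @return one-row tibble with `roa`, `sensitivity`, `precision`, `fnr`.
#' @export
agreement_scores <- function(m) {
  stopifnot(inherits(m, "mu_match"))
  if (m$tp + m$fn == 0 || m$tp + m$fp == 0)
    abort("empty reference or test train; scores undefined",
          class = "mudecomp_undefined_scores")
  tibble::tibble(roa = m$tp / (m$tp + m$fn + m$fp),
                 sensitivity = m$tp / (m$tp + m$fn),
                 precision = m$tp / (m$tp + m$fp),
                 fnr = m$fn / (m$tp + m$fn))
}

#' RMSE between two smoothed-rate paths
#'
#' @param test_rates,ref_rates equal-length series, pps, produced with the
#'   same windowing (see [smoothed_rates()]).
#' @return scalar RMSE, pps.
#' @export
rate_rmse <- function(test_rates, ref_rates) {
  if (length(test_rates) != length(ref_rates))
    abort("rate series have different lengths",
          class = "mudecomp_invalid_comparison")
  sqrt(mean((test_rates - ref_rates)^2))
}

#' Smoothed firing rate of a spike train
#'
#' Epoch-wise rate as displayed by the real-time feedback: the raw rate at
#' epoch k is the spike count over the trailing `window` epochs of
#' `epoch_ms` (8 x 125 ms = 1 s, so the count is directly in pps); the
#' smoothed rate is the mean of the last `smooth` raw values.
#'
#' @param spikes discharge sample indices (1-based).
#' @param n_samples record length in samples.
#' @param fs sampling rate, Hz.
#' @param epoch_ms epoch duration, ms.
#' @param window raw-rate window, epochs.
#' @param smooth number of raw values averaged.
#' @return tibble with `epoch`, `count`, `rate_raw`, `rate_smooth`.
#' @export
smoothed_rates <- function(spikes, n_samples, fs, epoch_ms = 125,
                           window = 8, smooth = 4) {
  esamp <- round(epoch_ms / 1000 * fs)
  n_epochs <- n_samples %/% esamp
  ep <- (spikes - 1L) %/% esamp + 1L
  counts <- tabulate(ep[ep <= n_epochs], nbins = n_epochs)
  raw <- vapply(seq_len(n_epochs), function(k)
    sum(counts[max(1L, k - window + 1L):k]), 0)
  sm <- vapply(seq_len(n_epochs), function(k)
    mean(raw[max(1L, k - smooth + 1L):k]), 0)
  tibble::tibble(epoch = seq_len(n_epochs), count = counts,
                 rate_raw = raw, rate_smooth = sm)
}

#' Score identified spike trains against simulated ground truth
#'
#' Matches each identified train to its best ground-truth unit (the one
#' maximising the rate of agreement, with constant-lag alignment) and returns
#' the agreement scores per identified unit.
#'
#' @param trains list of identified spike trains (sample indices) or a
#'   `mu_decomposition`.
#' @param truth a [simulate_contraction()] `sim_truth`.
#' @param fs sampling rate, Hz (taken from the truth by default).
#' @param tolerance_ms,max_lag_ms see [match_spike_trains()]. The default lag
#'   search here is wider (50 ms) than for test-vs-reference comparisons
#'   because convolutive source separation recovers each train as a delayed
#'   replica, with a delay of up to the extension factor plus the action
#'   potential duration.
#' @param truth_units optional pre-assigned truth unit per train (integer
#'   vector); when supplied the search is skipped and each train is scored
#'   against its assigned unit.
#' @return tibble with one row per identified unit: `unit`, `truth_unit`,
#'   `lag`, `tp`, `fp`, `fn`, `roa`, `sensitivity`, `precision`, `fnr`.
#' @export
score_against_truth <- function(trains, truth, fs = truth$sampling_rate,
                                tolerance_ms = 0.5, max_lag_ms = 50,
                                truth_units = NULL) {
  if (inherits(trains, "mu_decomposition")) trains <- trains$spike_trains
  stopifnot(inherits(truth, "sim_truth"))
  purrr::imap_dfr(trains, function(sp, nm) {
    uid <- if (is.character(nm) && grepl("^unit_", nm))
      as.integer(sub("unit_", "", nm)) else match(nm, names(trains))
    if (!length(sp)) {
      return(tibble::tibble(unit = uid, truth_unit = NA_integer_,
                            lag = NA_integer_, tp = 0L, fp = 0L, fn = NA_integer_,
                            roa = 0, sensitivity = 0, precision = NA_real_,
                            fnr = 1))
    }
    cand <- if (is.null(truth_units)) seq_along(truth$spike_trains)
            else truth_units[[match(nm, names(trains))]]
    best <- NULL; best_roa <- -1; best_u <- NA_integer_
    for (u in cand) {
      tr <- truth$spike_trains[[u]]
      if (length(tr) < 1) next
      m <- match_spike_trains(sp, tr, fs, tolerance_ms, align = TRUE,
                              max_lag_ms = max_lag_ms)
      roa <- m$tp / (m$tp + m$fn + m$fp)
      if (roa > best_roa) { best_roa <- roa; best <- m; best_u <- u }
    }
    if (is.null(best))
      return(tibble::tibble(unit = uid, truth_unit = NA_integer_,
                            lag = NA_integer_, tp = 0L, fp = length(sp),
                            fn = NA_integer_, roa = 0, sensitivity = NA_real_,
                            precision = 0, fnr = NA_real_))
    sc <- agreement_scores(best)
    tibble::tibble(unit = uid, truth_unit = best_u, lag = best$lag_applied,
                   tp = best$tp, fp = best$fp, fn = best$fn,
                   roa = sc$roa, sensitivity = sc$sensitivity,
                   precision = sc$precision, fnr = sc$fnr)
  })
}
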