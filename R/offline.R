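#' Offline decomposition of a baseline contraction
#'
#' Full calibration pipeline: electrode mask, signal extension
#' (`R = round(1000 / m)`), demeaning and whitening, then repeated
#' [extract_source()] / [detect_and_classify_peaks()] / [refine_by_cov_isi()]
#' over `n_sources` candidate sources with deflation, a silhouette gate
#' (default 0.90) and duplicate removal. For every accepted motor unit the
#' filter is stored together with the spike/noise centroids and everything
#' needed to re-apply it to unseen data (mask, extension factor, whitening
#' matrix, row means), so the result can be streamed with [init_stream()].
#'
#' @param rec an [new_emg_recording()] (isometric baseline contraction).
#' @param config a [mu_config()].
#' @param seed integer seed (initialisation fallback); identical seeds give
#'   bit-identical results.
#' @return A `mu_decomposition`: `filters` (list of motor unit filters with
#'   `w`, `w_deflation`, `spike_centroid`, `noise_centroid`, `sil`,
#'   `cov_isi`), `spike_trains`, `rejected` tibble, `calibration` artifacts
#'   and the config.
#' @examples
#' \donttest{
#' fx <- make_fixture("toy_two_units", seed = 1)
#' dec <- decompose_offline(fx$recording, mu_config(decomposition = list(n_sources = 4)))
#' tidy(dec)
#' }
#' @export
decompose_offline <- function(rec, config = mu_config(), seed = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  if (!is.null(seed)) set.seed(seed)
  dc <- config$decomposition
  masked <- apply_mask(rec)
  R <- default_extension_factor(nrow(masked$data), dc$extension_target)
  fs <- masked$sampling_rate
  excl_half <- round(0.002 * fs)           # init exclusion around claimed spikes
  peel_half <- R + round(0.015 * fs)       # spike-triggered support to peel

  # extension + whitening, arranged to keep at most one extended-size matrix
  # alive: the centered covariance is E E'/T - mu mu' (no centered copy), the
  # demeaning is done in place in chunks, and the extended matrix is freed as
  # soon as the whitened signal exists
  E <- extend_matrix(masked$data, R)
  T_len <- ncol(E)
  if (T_len <= nrow(E))
    warn("fewer samples than extended dimensions; whitening will be rank-limited")
  mu <- rowMeans(E)
  C <- tcrossprod(E) / T_len - outer(mu, mu)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  half_spec <- ev[seq.int(ceiling(length(ev) / 2) + 1L, length(ev))]
  keep <- ev > mean(half_spec)
  W <- t(eg$vectors[, keep, drop = FALSE]) / sqrt(ev[keep])
  for (j0 in seq(1L, T_len, by = 100000L)) {
    j1 <- min(T_len, j0 + 99999L)
    E[, j0:j1] <- E[, j0:j1] - mu
  }
  X <- W %*% E
  rm(E, C, eg); gc(FALSE)

  # Xres is the working copy that accepted units are peeled from (deflation in
  # the signal domain); final filters, centroids and silhouettes are always
  # recomputed on the untouched X so they match later re-application.
  Xres <- X
  # candidate initialisation looks at the *unwhitened* signal energy: after
  # whitening every sample has comparable norm, so maxima of the whitened
  # energy are noise outliers rather than large action potentials
  activity <- colSums(masked$data^2)
  B <- NULL                                # deflation basis (all extracted)
  filters <- list(); trains <- list()
  rejected <- tibble::tibble(source_id = integer(0), reason = character(0),
                             sil = numeric(0))
  reject <- function(id, reason, sil = NA_real_)
    dplyr::bind_rows(rejected, tibble::tibble(source_id = id, reason = reason,
                                              sil = sil))

  for (k in seq_len(dc$n_sources)) {
    if (all(!is.finite(activity))) break
    t0 <- which.max(activity)
    w0 <- Xres[, t0]
    # the init instant is consumed whether or not the candidate survives,
    # so failed candidates cannot pin the loop to one spot
    activity[max(1L, t0 - excl_half):min(length(activity), t0 + excl_half)] <- -Inf
    es <- extract_source_core(Xres, w0, prior_filters = B,
                              max_iter = dc$max_iter, tol = dc$tol,
                              contrast = dc$contrast)
    B <- cbind(B, es$w)
    pt <- tryCatch(detect_and_classify_peaks(es$source^2, fs, dc$min_separation_ms),
                   error = function(e) NULL)
    if (is.null(pt)) { rejected <- reject(k, "insufficient-peaks"); next }
    ref <- tryCatch(refine_core(Xres, fs, es$w, pt,
                                max_iter = dc$max_refine_iter,
                                min_separation_ms = dc$min_separation_ms),
                    error = function(e) NULL)
    if (is.null(ref) || length(ref$spikes) < 2) {
      rejected <- reject(k, "insufficient-peaks"); next
    }
    # final filter and pulse train on the original whitened data, polished by
    # a short CoV refinement there so the stored filter is the one whose
    # re-application reproduces the stored train
    wf <- sta_filter(X, ref$spikes)
    ptf <- tryCatch(detect_and_classify_peaks(as.vector(crossprod(wf, X))^2,
                                              fs, dc$min_separation_ms),
                    error = function(e) NULL)
    if (is.null(ptf)) { rejected <- reject(k, "insufficient-peaks"); next }
    fin <- tryCatch(refine_core(X, fs, wf, ptf, max_iter = 5,
                                min_separation_ms = dc$min_separation_ms),
                    error = function(e) NULL)
    if (is.null(fin)) { rejected <- reject(k, "insufficient-peaks"); next }
    wf <- fin$w; ptf <- fin$pulse_train
    train <- ptf$peaks$sample[ptf$peaks$class == "spike"]
    silf <- fin$sil
    # claimed discharge times no longer seed new candidates
    idx <- outer(train, -excl_half:excl_half, "+")
    idx <- idx[idx >= 1 & idx <= length(activity)]
    activity[idx] <- -Inf
    if (length(train) < 2 || !accept_filter(silf, dc$sil_threshold)) {
      rejected <- reject(k, "low-SIL", silf)
      next
    }
    # physiological plausibility: during steady isometric force a real motor
    # unit discharges regularly; trains with erratic interspike intervals or
    # too few discharges are refinement artifacts, the programmatic
    # counterpart of the operator discarding pulse trains without clear
    # separation
    if (length(train) < dc$min_spikes || cov_isi(train) > dc$max_cov_isi) {
      rejected <- reject(k, "implausible-train", silf)
      next
    }
    filters[[length(filters) + 1L]] <- structure(
      list(w = wf, w_deflation = es$w,
           spike_centroid = ptf$spike_centroid,
           noise_centroid = ptf$noise_centroid,
           sil = silf, cov_isi = cov_isi(train),
           source_id = k, converged = es$converged),
      class = "mu_filter")
    trains[[length(trains) + 1L]] <- train
    # peel the accepted unit's spike-triggered contribution out of Xres so
    # later candidates are not captured by the units already found (inlined
    # so the column updates stay in place)
    for (tau in -peel_half:peel_half) {
      cols <- ref$spikes + tau
      cols <- cols[cols >= 1 & cols <= T_len]
      if (length(cols) < 2) next
      Xres[, cols] <- Xres[, cols] - rowMeans(Xres[, cols, drop = FALSE])
    }
  }
  rm(Xres); gc(FALSE)

  res <- structure(list(
    filters = filters, spike_trains = trains, rejected = rejected,
    calibration = list(mask = rec$mask, R = R, W = W,
                       row_means = mu,
                       retained_dims = nrow(W),
                       sampling_rate = fs, m = nrow(masked$data)),
    config = config, seed = seed
  ), class = "mu_decomposition")
  remove_duplicates(res, dc$duplicate_share, dc$duplicate_tol_ms,
                    dc$duplicate_lag_ms)
}

#' Remove duplicate motor units
#'
#' Any pair of accepted spike trains sharing more than `share_threshold` of
#' their discharges (within the tolerance, after constant-lag alignment)
#' keeps only the higher-silhouette member; the other is moved to the
#' rejected list with reason `"duplicate"`.
#'
#' @param result a `mu_decomposition`.
#' @param share_threshold shared fraction (of the shorter train) above which
#'   a pair is a duplicate.
#' @param tol_ms matching tolerance, ms.
#' @param lag_ms constant-lag search range, ms.
#' @return The pruned `mu_decomposition`.
#' @export
remove_duplicates <- function(result, share_threshold = 0.3, tol_ms = 0.5,
                              lag_ms = 10) {
  stopifnot(inherits(result, "mu_decomposition"))
  n <- length(result$filters)
  if (n < 2) return(result)
  fs <- result$calibration$sampling_rate
  drop <- logical(n)
  for (i in seq_len(n - 1)) {
    if (drop[i]) next
    for (j in seq.int(i + 1, n)) {
      if (drop[j]) next
      m <- match_spike_trains(result$spike_trains[[j]], result$spike_trains[[i]],
                              fs, tolerance_ms = tol_ms, align = TRUE,
                              max_lag_ms = lag_ms)
      share <- m$tp / min(length(result$spike_trains[[i]]),
                          length(result$spike_trains[[j]]))
      if (share > share_threshold) {
        # keep the member with the more regular discharge pattern (lowest CoV
        # of the interspike intervals), the convention of the decomposition
        # pipeline this implements; ties fall back to the silhouette
        cv_i <- cov_isi(result$spike_trains[[i]])
        cv_j <- cov_isi(result$spike_trains[[j]])
        victim <- if (cv_i < cv_j ||
                      (cv_i == cv_j &&
                       result$filters[[i]]$sil >= result$filters[[j]]$sil)) j else i
        drop[victim] <- TRUE
        result$rejected <- dplyr::bind_rows(
          result$rejected,
          tibble::tibble(source_id = result$filters[[victim]]$source_id,
                         reason = "duplicate",
                         sil = result$filters[[victim]]$sil))
        if (victim == i) break
      }
    }
  }
  result$filters <- result$filters[!drop]
  result$spike_trains <- result$spike_trains[!drop]
  names(result$spike_trains) <- paste0("unit_", seq_along(result$spike_trains))
  result
}

#' @export
print.mu_decomposition <- function(x, ...) {
  cat(sprintf("<mu_decomposition> %d accepted motor units (%d candidates rejected)\n",
              length(x$filters), nrow(x$rejected)))
  if (length(x$filters))
    cat(sprintf("  SIL %.3f-%.3f, extension R = %d, %d whitened dims\n",
                min(vapply(x$filters, `[[`, 1, "sil")),
                max(vapply(x$filters, `[[`, 1, "sil")),
                x$calibration$R, x$calibration$retained_dims))
  invisible(x)
}

#' @describeIn decompose_offline one row per accepted unit (`unit`, `sil`,
#'   `cov_isi`, `n_spikes`, `mean_rate_pps`, centroids).
#' @param x,object a `mu_decomposition`.
#' @param ... unused.
#' @export
tidy.mu_decomposition <- function(x, ...) {
  fs <- x$calibration$sampling_rate
  purrr::map2_dfr(x$filters, x$spike_trains, function(f, sp) {
    tibble::tibble(sil = f$sil, cov_isi = f$cov_isi, n_spikes = length(sp),
                   mean_rate_pps = if (length(sp) > 1)
                     fs / mean(diff(sp)) else NA_real_,
                   spike_centroid = f$spike_centroid,
                   noise_centroid = f$noise_centroid,
                   converged = f$converged)
  }) |>
    dplyr::mutate(unit = dplyr::row_number(), .before = 1)
}

#' @describeIn decompose_offline one-row summary.
#' @export
glance.mu_decomposition <- function(x, ...) {
  tibble::tibble(
    n_accepted = length(x$filters),
    n_rejected_sil = sum(x$rejected$reason == "low-SIL"),
    n_rejected_duplicate = sum(x$rejected$reason == "duplicate"),
    mean_sil = if (length(x$filters))
      mean(vapply(x$filters, `[[`, 1, "sil")) else NA_real_,
    extension_factor = x$calibration$R,
    retained_dims = x$calibration$retained_dims
  )
}

#' @describeIn decompose_offline raster plot of the accepted spike trains.
#' @export
autoplot.mu_decomposition <- function(object, ...) {
  fs <- object$calibration$sampling_rate
  df <- purrr::imap_dfr(object$spike_trains, function(sp, nm) {
    tibble::tibble(unit = as.integer(sub("unit_", "", nm)), time_s = sp / fs)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$unit)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "motor unit")
}
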