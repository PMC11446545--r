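#' Detect and classify pulse-train peaks
#'
#' Local maxima of the (squared) pulse train with a minimum separation
#' (default 25 ms, the physiological interspike floor), followed by a
#' two-class k-means on the peak amplitudes: the class with the larger
#' centroid is labelled `spike`, the other `noise`.
#'
#' @param values non-negative pulse-train samples (squared source).
#' @param sampling_rate Hz.
#' @param min_separation_ms minimum peak separation, ms.
#' @return A `pulse_train`: `values`, `peaks` tibble (`sample`, `amplitude`,
#'   `class`), `spike_centroid`, `noise_centroid`, `sampling_rate`.
#' @export
detect_and_classify_peaks <- function(values, sampling_rate,
                                      min_separation_ms = 25) {
  sep <- round(min_separation_ms / 1000 * sampling_rate)
  pk <- causal_peaks(values, sep)
  if (nrow(pk) < 2)
    abort("fewer than 2 peaks in the pulse train",
          class = "mudecomp_insufficient_peaks")
  amps <- pk$amplitude
  if (diff(range(amps)) == 0)
    abort("all peaks equal; spike/noise classes are not separable",
          class = "mudecomp_insufficient_separation")
  km <- kmeans(amps, centers = matrix(range(amps), ncol = 1))
  spike_cl <- which.max(km$centers)
  pk$class <- ifelse(km$cluster == spike_cl, "spike", "noise")
  structure(list(values = values, peaks = pk,
                 spike_centroid = max(km$centers),
                 noise_centroid = min(km$centers),
                 sampling_rate = sampling_rate,
                 min_separation_ms = min_separation_ms),
            class = "pulse_train")
}

#' Silhouette value of a pulse train
#'
#' Normalised distance between the spike and noise peak classes after the
#' two-class k-means:
#' `SIL = (D_between - D_within) / max(D_between, D_within)`, where
#' `D_within` is the sum over all peaks of the absolute distance to their own
#' class centroid and `D_between` the sum of the absolute distances to the
#' other class's centroid (the definition used throughout the convolutive
#' decomposition literature). Ranges over \[-1, 1\]; values near 1 indicate
#' spikes well separated from the noise, and about 0.9 is the usual
#' acceptance gate.
#'
#' @param pt a [detect_and_classify_peaks()] result.
#' @return scalar silhouette value.
#' @export
compute_sil <- function(pt) {
  stopifnot(inherits(pt, "pulse_train"))
  spk <- pt$peaks$amplitude[pt$peaks$class == "spike"]
  noi <- pt$peaks$amplitude[pt$peaks$class == "noise"]
  if (!length(spk) || !length(noi))
    abort("both peak classes must be non-empty",
          class = "mudecomp_undefined_sil")
  cs <- pt$spike_centroid; cn <- pt$noise_centroid
  d_within <- sum(abs(spk - cs)) + sum(abs(noi - cn))
  d_between <- sum(abs(spk - cn)) + sum(abs(noi - cs))
  dmax <- max(d_between, d_within)
  if (dmax == 0) return(0)
  (d_between - d_within) / dmax
}

#' Extract one source by fixed-point ICA
#'
#' Iterates the fixed-point update
#' `w <- E\{x g(w'x)\} - E\{g'(w'x)\} w` on the whitened signal with the
#' chosen contrast (`"square"`, i.e. `g(x) = x^2`, seeks skewed sparse
#' sources; `"logcosh"` selectable), orthogonalising against previously
#' extracted vectors (deflation) and renormalising at every iteration. Stops
#' when the separation vector changes by less than `tol` between iterations
#' (`|<w_k, w_{k-1}>| - 1` in magnitude) or after `max_iter` iterations.
#'
#' @param xw an [whiten_emg()] result.
#' @param w0 initial vector; default: the whitened observation at the sample
#'   of largest summed squared activity not excluded by `exclude`.
#' @param prior_filters matrix (retained x k) of previously extracted vectors
#'   to deflate against.
#' @param max_iter,tol convergence controls.
#' @param contrast `"square"` or `"logcosh"`.
#' @param exclude integer sample indices excluded from the activity-based
#'   initialisation (times claimed by accepted units).
#' @return list with `w` (unit norm), `source` (the projected source),
#'   `converged`, `n_iter`.
#' @export
extract_source <- function(xw, w0 = NULL, prior_filters = NULL,
                           max_iter = 100, tol = 1e-4,
                           contrast = c("square", "logcosh"),
                           exclude = NULL) {
  stopifnot(inherits(xw, "ext_whitened"))
  contrast <- match.arg(contrast)
  if (tol <= 0) abort("tol must be positive", class = "mudecomp_invalid_argument")
  X <- xw$whitened
  if (is.null(w0)) {
    a <- col_sq_sums(X)
    if (!is.null(exclude)) a[exclude[exclude >= 1 & exclude <= ncol(X)]] <- -Inf
    w0 <- X[, which.max(a)]
  }
  extract_source_core(X, w0, prior_filters, max_iter, tol, contrast)
}

extract_source_core <- function(X, w0, prior_filters = NULL, max_iter = 100,
                                tol = 1e-4, contrast = "square") {
  T_len <- ncol(X)
  B <- prior_filters
  if (!is.null(B)) B <- as.matrix(B)
  orth <- function(w) if (is.null(B)) w else w - B %*% crossprod(B, w)
  w <- orth(w0); w <- w / sqrt(sum(w^2))
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    s <- as.vector(crossprod(w, X))
    if (contrast == "square") {
      wn <- X %*% (s^2) / T_len - 2 * mean(s) * w
    } else {
      g <- tanh(s)
      wn <- X %*% g / T_len - mean(1 - g^2) * w
    }
    wn <- orth(wn)
    wn <- wn / sqrt(sum(wn^2))
    if (abs(abs(sum(wn * w)) - 1) < tol) { w <- wn; converged <- TRUE; break }
    w <- wn
  }
  list(w = as.vector(w), source = as.vector(crossprod(w, X)),
       converged = converged, n_iter = it)
}

# spike-triggered average filter, unit norm
sta_filter <- function(X, spikes) {
  w <- rowMeans(X[, spikes, drop = FALSE])
  w / sqrt(sum(w^2))
}
# column sums of squares, chunked to bound the transient copy
col_sq_sums <- function(X, chunk = 100000L) {
  T_len <- ncol(X)
  out <- numeric(T_len)
  for (j0 in seq(1L, T_len, by = chunk)) {
    j1 <- min(T_len, j0 + chunk - 1L)
    out[j0:j1] <- colSums(X[, j0:j1, drop = FALSE]^2)
  }
  out
}

cov_isi <- function(spikes) {
  if (length(spikes) < 3) return(Inf)
  isi <- diff(spikes)
  sd(isi) / mean(isi)
}

#' Refine a separation vector by minimising the CoV of the ISIs
#'
#' Iteratively recomputes the separation vector as the spike-triggered
#' average of the whitened observations at the current discharge times,
#' renormalises, re-detects and re-classifies peaks, and keeps the iterate
#' with the smallest coefficient of variation of the interspike intervals
#' (regular discharge is the physiological expectation during steady
#' isometric force). The returned CoV never exceeds the input CoV.
#'
#' @param w current separation vector.
#' @param xw the [whiten_emg()] signal.
#' @param pt the current [detect_and_classify_peaks()] pulse train.
#' @param max_iter maximum refinement passes.
#' @param min_separation_ms peak separation, ms.
#' @return list with `w`, `spikes` (discharge samples), `pulse_train`, `sil`,
#'   `cov_isi`, `collapsed` (TRUE when the spike count dropped below 2 and
#'   the best previous iterate was returned).
#' @export
refine_by_cov_isi <- function(w, xw, pt, max_iter = 20, min_separation_ms = 25) {
  stopifnot(inherits(xw, "ext_whitened"))
  refine_core(xw$whitened, xw$sampling_rate, w, pt, max_iter, min_separation_ms)
}

refine_core <- function(X, fs, w, pt, max_iter = 20, min_separation_ms = 25) {
  stopifnot(inherits(pt, "pulse_train"))
  spikes <- pt$peaks$sample[pt$peaks$class == "spike"]
  if (length(spikes) < 2)
    abort("need at least 2 spikes to refine", class = "mudecomp_insufficient_peaks")
  best <- list(w = w, pt = pt, spikes = spikes, cv = cov_isi(spikes))
  collapsed <- FALSE
  for (it in seq_len(max_iter)) {
    w2 <- sta_filter(X, spikes)
    s2 <- as.vector(crossprod(w2, X))^2
    pt2 <- tryCatch(detect_and_classify_peaks(s2, fs, min_separation_ms),
                    error = function(e) NULL)
    if (is.null(pt2)) { collapsed <- TRUE; break }
    spikes2 <- pt2$peaks$sample[pt2$peaks$class == "spike"]
    if (length(spikes2) < 2) { collapsed <- TRUE; break }
    cv2 <- cov_isi(spikes2)
    if (cv2 < best$cv || (is.infinite(best$cv) && is.infinite(cv2)))
      best <- list(w = w2, pt = pt2, spikes = spikes2, cv = cv2)
    if (identical(spikes2, spikes)) break
    spikes <- spikes2
  }
  list(w = best$w, spikes = best$spikes, pulse_train = best$pt,
       sil = compute_sil(best$pt), cov_isi = best$cv, collapsed = collapsed)
}

#' Silhouette acceptance gate
#'
#' @param sil silhouette value in \[-1, 1\].
#' @param threshold acceptance threshold (default 0.90); the comparison is
#'   inclusive.
#' @return logical.
#' @export
accept_filter <- function(sil, threshold = 0.9) {
  stopifnot(is.numeric(sil), sil >= -1, sil <= 1)
  sil >= threshold
}
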