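#' Open an edit session for one motor unit
#'
#' Programmatic spike-train editing: outlier discharges are flagged,
#' discharges added or removed, the separation vector is then recomputed as
#' the spike-triggered average over the edited train and re-applied to the
#' whole signal, and the edit is committed only if the silhouette value
#' improves or remains at/above the acceptance threshold.
#'
#' @param xw the [whiten_emg()] reference signal the unit was identified
#'   from.
#' @param train current discharge samples (strictly increasing).
#' @param threshold silhouette acceptance gate.
#' @param min_separation_ms peak separation, ms.
#' @return An `edit_session` with the committed `train`, the derived filter
#'   `w`, `pulse_train`, `sil` and an empty `history`. The session's `sil`
#'   is the silhouette of the *tracked train* (pulse-train peaks coinciding
#'   with its discharges form the spike class), so false positives sitting
#'   on low peaks depress it and successful edits raise it.
#' @export
edit_session <- function(xw, train, threshold = 0.9, min_separation_ms = 25) {
  stopifnot(inherits(xw, "ext_whitened"))
  train <- sort(as.integer(train))
  if (length(train) < 2)
    abort("need at least 2 discharges to open a session",
          class = "mudecomp_invalid_argument")
  d <- session_derive(xw, train, min_separation_ms)
  structure(list(xw = xw, train = train, pending = train,
                 w = d$w, pulse_train = d$pt, sil = d$sil,
                 threshold = threshold,
                 min_separation_ms = min_separation_ms,
                 history = tibble::tibble(op = character(0),
                                          indices = list(),
                                          sil_before = numeric(0),
                                          sil_after = numeric(0),
                                          committed = logical(0))),
            class = "edit_session")
}

# filter + pulse train + SIL derived from a train by spike-triggered averaging
session_derive <- function(xw, train, min_separation_ms) {
  w <- rowMeans(xw$whitened[, train, drop = FALSE])
  w <- w / sqrt(sum(w^2))
  s2 <- as.vector(crossprod(w, xw$whitened))^2
  pt <- detect_and_classify_peaks(s2, xw$sampling_rate, min_separation_ms)
  list(w = as.vector(w), pt = pt,
       sil = train_sil(pt, train, xw$sampling_rate))
}

# silhouette of a *specific* discharge train: peaks coinciding with a train
# discharge (within 1 ms) form the spike class, all others the noise class.
# This is the quality the editing workflow tracks — false positives sit on
# low pulse-train peaks and visibly depress it, where a re-fit k-means would
# simply reassign them. Falls back to the k-means silhouette in degenerate
# cases.
train_sil <- function(pt, train, fs) {
  tol <- max(1L, round(0.001 * fs))
  near <- vapply(pt$peaks$sample, function(s) min(abs(train - s)) <= tol,
                 NA)
  if (!any(near) || all(near)) return(compute_sil(pt))
  ptc <- pt
  ptc$peaks$class <- ifelse(near, "spike", "noise")
  ptc$spike_centroid <- mean(ptc$peaks$amplitude[near])
  ptc$noise_centroid <- mean(ptc$peaks$amplitude[!near])
  compute_sil(ptc)
}

#' @export
print.edit_session <- function(x, ...) {
  pend <- length(x$pending) - length(x$train)
  cat(sprintf("<edit_session> %d discharges, SIL %.3f, %+d pending, %d edits in history\n",
              length(x$train), x$sil, pend, nrow(x$history)))
  invisible(x)
}

#' Flag outlier discharges
#'
#' Discharges whose adjacent instantaneous rates (1/ISI) fall outside the
#' physiological bounds: above `rate_max_pps` (default 50 pps — typically
#' double detections; the later discharge of the offending pair is flagged)
#' or below `rate_min_pps` (default 2 pps on a plateau — typically a run of
#' missed discharges; the discharge ending the gap is flagged for
#' inspection).
#'
#' @param train discharge samples, or an `edit_session` (its pending train).
#' @param fs sampling rate, Hz (taken from the session when given one).
#' @param rate_max_pps,rate_min_pps bounds, pps.
#' @return tibble with `index` (position in the train), `sample`, `rate_pps`,
#'   `reason`.
#' @export
flag_outlier_discharges <- function(train, fs = NULL, rate_max_pps = 50,
                                    rate_min_pps = 2) {
  if (inherits(train, "edit_session")) {
    fs <- train$xw$sampling_rate
    train <- train$pending
  }
  if (!length(train))
    abort("train is empty", class = "mudecomp_invalid_argument")
  if (length(train) < 2)
    return(tibble::tibble(index = integer(0), sample = integer(0),
                          rate_pps = numeric(0), reason = character(0)))
  rate <- fs / diff(train)
  hi <- which(rate > rate_max_pps)
  lo <- which(rate < rate_min_pps)
  tibble::tibble(index = c(hi + 1L, lo + 1L),
                 sample = train[c(hi + 1L, lo + 1L)],
                 rate_pps = c(rate[hi], rate[lo]),
                 reason = c(rep("high_rate", length(hi)),
                            rep("low_rate", length(lo)))) |>
    dplyr::arrange(.data$index)
}

#' Stage an edit
#'
#' Adds or removes discharge times on the session's pending train. Edits are
#' not committed until [recompute_and_validate()] re-derives the filter and
#' checks the silhouette. Adding at an existing index is a no-op with a
#' warning; adding closer than the minimum separation to a neighbour is
#' rejected.
#'
#' @param session an [edit_session()].
#' @param op `"add"` or `"remove"`.
#' @param sample_indices discharge samples to add or remove.
#' @return the updated session (pending).
#' @export
apply_edit <- function(session, op = c("add", "remove"), sample_indices) {
  stopifnot(inherits(session, "edit_session"))
  op <- match.arg(op)
  sample_indices <- as.integer(sample_indices)
  n_samp <- ncol(session$xw$whitened)
  if (any(sample_indices < 1L) || any(sample_indices > n_samp))
    abort("sample index outside the record", class = "mudecomp_invalid_argument")
  pend <- session$pending
  sep <- round(session$min_separation_ms / 1000 * session$xw$sampling_rate)
  if (op == "add") {
    for (s in sample_indices) {
      if (s %in% pend) { warn(sprintf("discharge at %d already present", s)); next }
      if (any(abs(pend - s) < sep)) {
        warn(sprintf("discharge at %d violates the %g ms separation; rejected",
                     s, session$min_separation_ms))
        next
      }
      pend <- sort(c(pend, s))
    }
  } else {
    missing <- setdiff(sample_indices, pend)
    if (length(missing))
      warn(sprintf("%d discharge(s) not present; ignored", length(missing)))
    pend <- setdiff(pend, sample_indices)
  }
  session$pending <- pend
  session$history <- dplyr::bind_rows(
    session$history,
    tibble::tibble(op = op, indices = list(sample_indices),
                   sil_before = session$sil, sil_after = NA_real_,
                   committed = NA))
  session
}

#' Recompute the filter and validate pending edits
#'
#' Re-derives the separation vector by spike-triggered averaging over the
#' pending train, re-applies it to the whole signal to generate a new pulse
#' train and discharge set, and commits the edit only if the new silhouette
#' is at least the previous one or at/above the threshold; otherwise the
#' pending edits are rolled back.
#'
#' @param session an [edit_session()] with pending edits.
#' @return the session, committed or rolled back; `$last_commit` reports the
#'   outcome.
#' @export
recompute_and_validate <- function(session) {
  stopifnot(inherits(session, "edit_session"))
  sil_old <- session$sil
  outcome <- NULL
  if (!length(session$pending)) {
    outcome <- list(committed = FALSE, reason = "empty edited train",
                    sil_before = sil_old, sil_after = NA_real_)
  } else {
    d <- tryCatch(session_derive(session$xw, session$pending,
                                 session$min_separation_ms),
                  error = function(e) NULL)
    if (is.null(d)) {
      outcome <- list(committed = FALSE, reason = "degenerate pulse train",
                      sil_before = sil_old, sil_after = NA_real_)
    } else {
      # the state a commit would adopt: the re-derived discharge train
      # (recovering clearly distinguishable missed spikes, dropping false
      # ones) and its silhouette
      new_train <- d$pt$peaks$sample[d$pt$peaks$class == "spike"]
      sil_new <- train_sil(d$pt, new_train, session$xw$sampling_rate)
      if (sil_new >= sil_old || sil_new >= session$threshold) {
        session$w <- d$w
        session$pulse_train <- d$pt
        session$sil <- sil_new
        session$train <- new_train
        session$pending <- new_train
        outcome <- list(committed = TRUE, reason = "silhouette maintained",
                        sil_before = sil_old, sil_after = sil_new)
      } else {
        outcome <- list(committed = FALSE,
                        reason = sprintf("SIL dropped %.3f -> %.3f",
                                         sil_old, sil_new),
                        sil_before = sil_old, sil_after = sil_new)
      }
    }
  }
  if (!outcome$committed) session$pending <- session$train
  n <- nrow(session$history)
  if (n > 0 && is.na(session$history$committed[n])) {
    open_rows <- which(is.na(session$history$committed))
    session$history$committed[open_rows] <- outcome$committed
    session$history$sil_after[open_rows] <- outcome$sil_after
  }
  session$last_commit <- outcome
  session
}

#' Serialise an edit history to JSON lines
#'
#' @param session an [edit_session()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edit_log <- function(session, path) {
  stopifnot(inherits(session, "edit_session"))
  lines <- vapply(seq_len(nrow(session$history)), function(i) {
    h <- session$history[i, ]
    jsonlite::toJSON(list(op = h$op, indices = h$indices[[1]],
                          sil_before = h$sil_before, sil_after = h$sil_after,
                          committed = h$committed),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
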