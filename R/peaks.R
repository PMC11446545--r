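# Causal peak detection with a minimum separation.
#
# Local maxima (strictly greater than the previous sample, at least as large
# as the next) are scanned in time order; a candidate closer than `sep`
# samples to the last kept peak replaces it if larger, otherwise it is
# dropped. A kept peak becomes final once the scan has passed `sep` samples
# beyond it (no later candidate can replace it), which lets the identical
# rule run either over a whole record or incrementally over streamed epochs
# with a carried tail — the two produce the same peak set by construction.

new_peak_state <- function() {
  list(buf = numeric(0), buf_start = 1L,
       last_time = -Inf, last_amp = -Inf)
}

# vals: new samples (absolute indices buf_start + length(buf) + 0:...)
# Returns list(peaks = tibble(sample, amplitude) finalized now, state = ...)
peak_step <- function(state, vals, sep, flush = FALSE) {
  sep <- as.integer(sep)
  buf <- c(state$buf, vals)
  start <- state$buf_start
  n <- length(buf)
  finalized_t <- integer(0); finalized_a <- numeric(0)
  if (n >= 3) {
    i <- 2:(n - 1)
    is_max <- buf[i] > buf[i - 1] & buf[i] >= buf[i + 1]
    cand <- i[is_max]
    lt <- state$last_time; la <- state$last_amp
    kept_t <- integer(0); kept_a <- numeric(0)
    for (ci in cand) {
      t_abs <- start + ci - 1L
      if (t_abs <= lt) next                      # already decided / finalized
      a <- buf[ci]
      if (t_abs - lt >= sep) {
        kept_t <- c(kept_t, t_abs); kept_a <- c(kept_a, a)
        lt <- t_abs; la <- a
      } else if (a > la) {                       # replace pending peak
        k <- length(kept_t)
        if (k > 0) { kept_t[k] <- t_abs; kept_a[k] <- a }
        else { kept_t <- t_abs; kept_a <- a }
        lt <- t_abs; la <- a
      }
    }
    end_abs <- start + n - 1L
    fin <- if (flush) rep(TRUE, length(kept_t)) else kept_t <= end_abs - sep
    finalized_t <- kept_t[fin]; finalized_a <- kept_a[fin]
  }
  end_abs <- start + n - 1L
  if (flush) {
    state$buf <- numeric(0); state$buf_start <- end_abs + 1L
  } else {
    keep_from <- max(1L, n - sep - 1L)           # tail: sep + 2 samples
    state$buf <- buf[keep_from:n]
    state$buf_start <- start + keep_from - 1L
  }
  if (length(finalized_t)) {
    state$last_time <- finalized_t[length(finalized_t)]
    state$last_amp <- finalized_a[length(finalized_a)]
  }
  list(peaks = tibble::tibble(sample = finalized_t, amplitude = finalized_a),
       state = state)
}

# whole-record peak detection (single flushed step)
causal_peaks <- function(values, sep) {
  peak_step(new_peak_state(), values, sep, flush = TRUE)$peaks
}
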