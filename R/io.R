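#' Write / read an EMG recording container
#'
#' A recording is persisted as a directory: `emg.feather` (Arrow IPC, one
#' column per channel — bit-exact round trip, readable from Python via
#' pyarrow), `meta.json` (sampling rate, array geometry, mask, free-form
#' metadata) and, when available, `force.feather` and `truth.json`
#' (ground-truth discharge samples per unit). Small delimited-text fixtures
#' (channels x samples with a header line, `.tsv`) are also accepted by
#' `read_recording()`.
#'
#' @param rec an [new_emg_recording()].
#' @param path directory to create (or, for reading, an existing container
#'   directory or a `.tsv` file).
#' @param truth optional `sim_truth` stored alongside.
#' @param force optional force trace.
#' @return `write_recording()`: `path`, invisibly. `read_recording()`: an
#'   `emg_recording` (with `$truth` spike trains in `meta` when present).
#' @export
write_recording <- function(rec, path, truth = NULL, force = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(t(rec$data))
  names(df) <- sprintf("ch%03d", seq_len(nrow(rec$data)))
  arrow::write_feather(df, file.path(path, "emg.feather"))
  meta <- list(sampling_rate = rec$sampling_rate,
               n_channels = nrow(rec$data),
               mask = rec$mask,
               array = if (!is.null(rec$array)) unclass(rec$array),
               meta = rec$meta[setdiff(names(rec$meta), "mask_applied")])
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(force))
    arrow::write_feather(data.frame(force = force),
                         file.path(path, "force.feather"))
  if (!is.null(truth))
    jsonlite::write_json(truth$spike_trains, file.path(path, "truth.json"),
                         digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @param sampling_rate sampling rate for text fixtures that carry none, Hz.
#' @export
read_recording <- function(path, sampling_rate = 2048) {
  if (dir.exists(path)) {
    emg_file <- file.path(path, "emg.feather")
    meta_file <- file.path(path, "meta.json")
    if (!file.exists(emg_file))
      abort("container has no EMG payload", class = "mudecomp_invalid_container")
    if (!file.exists(meta_file))
      abort("container has no metadata", class = "mudecomp_invalid_container")
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    if (is.null(meta$sampling_rate))
      abort("container metadata lacks sampling_rate",
            class = "mudecomp_invalid_container")
    df <- arrow::read_feather(emg_file)
    arr <- if (!is.null(meta$array))
      structure(meta$array, class = "electrode_array")
    m <- t(as.matrix(df))
    dimnames(m) <- NULL
    rec <- new_emg_recording(m, meta$sampling_rate, arr,
                             mask = meta$mask %||% rep(TRUE, ncol(df)),
                             meta = as.list(meta$meta))
    truth_file <- file.path(path, "truth.json")
    if (file.exists(truth_file))
      rec$meta$truth <- lapply(jsonlite::read_json(truth_file,
                                                   simplifyVector = TRUE),
                               as.integer)
    rec
  } else if (file.exists(path)) {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    new_emg_recording(as.matrix(df), sampling_rate)
  } else {
    abort(sprintf("no container at '%s'", path),
          class = "mudecomp_invalid_container")
  }
}

#' Persist / load motor unit filters
#'
#' The whole `mu_decomposition` (filters, centroids, silhouettes and every
#' calibration artifact needed to re-apply them bit-exactly: mask, extension
#' factor, whitening matrix, row means) is serialised to RDS.
#'
#' @param decomp a [decompose_offline()] result.
#' @param path file path.
#' @return `write_filters()`: `path`, invisibly; `read_filters()`: the
#'   `mu_decomposition`.
#' @export
write_filters <- function(decomp, path) {
  stopifnot(inherits(decomp, "mu_decomposition"))
  saveRDS(decomp, path)
  invisible(path)
}

#' @rdname write_filters
#' @export
read_filters <- function(path) {
  decomp <- readRDS(path)
  if (!inherits(decomp, "mu_decomposition"))
    abort("file does not contain motor unit filters",
          class = "mudecomp_invalid_container")
  decomp
}

#' Persist / load an electrode mask
#'
#' JSON schema: `{"mask": [true, ...], "created_from": "<file>",
#' "n_channels": 64}`.
#'
#' @param mask logical vector (`TRUE` = keep).
#' @param path file path.
#' @param created_from provenance note.
#' @return `write_mask()`: `path`, invisibly; `read_mask()`: the logical
#'   mask with attributes.
#' @export
write_mask <- function(mask, path, created_from = "") {
  jsonlite::write_json(list(mask = as.logical(mask),
                            created_from = created_from,
                            n_channels = length(mask)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$mask) || length(obj$mask) != obj$n_channels)
    abort("invalid mask file", class = "mudecomp_invalid_container")
  structure(as.logical(obj$mask), created_from = obj$created_from)
}

#' Write identified discharges to CSV
#'
#' One row per discharge: `unit`, `sample`, `time_s`, `epoch`.
#'
#' @param spikes a tibble with those columns (e.g. from
#'   [stream_recording()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  readr::write_csv(spikes[, intersect(c("unit", "sample", "time_s", "epoch"),
                                      names(spikes))], path)
  invisible(path)
}
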