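#' Muscle anatomy parameters
#'
#' Cylindrical muscle volume with parallel fibres, separated from the
#' recording surface by subcutaneous and skin layers. Defaults: 10 mm muscle
#' radius, 4 mm subcutaneous layer, 1 mm skin, 400 fibres/mm^2.
#'
#' @param muscle_radius muscle radius, mm.
#' @param subcutaneous_thickness subcutaneous layer thickness, mm.
#' @param skin_thickness skin thickness, mm.
#' @param fibre_density fibres per mm^2.
#' @return An object of class `muscle_anatomy`.
#' @export
muscle_anatomy <- function(muscle_radius = 10, subcutaneous_thickness = 4,
                           skin_thickness = 1, fibre_density = 400) {
  vals <- c(muscle_radius, subcutaneous_thickness, skin_thickness, fibre_density)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("all anatomy parameters must be positive", class = "mudecomp_invalid_argument")
  structure(list(muscle_radius = muscle_radius,
                 subcutaneous_thickness = subcutaneous_thickness,
                 skin_thickness = skin_thickness,
                 fibre_density = fibre_density),
            class = "muscle_anatomy")
}

#' Electrode array geometry
#'
#' Either a surface grid (default 13 rows x 5 columns, 4 mm inter-electrode
#' distance, one corner electrode absent so 64 of the 65 positions are
#' active) or an intramuscular linear array (default 16 electrodes, 1 mm
#' inter-electrode distance, inserted at 30 degrees along the longitudinal
#' direction toward the muscle centre).
#'
#' @param kind `"surface_grid"` or `"intramuscular_array"`.
#' @param n_rows,n_cols grid extent (surface) or `n_rows` electrodes in a
#'   single line (intramuscular, `n_cols = 1`).
#' @param inter_electrode_distance mm.
#' @param missing_electrodes integer indices of absent electrodes (for the
#'   default surface grid, the corner position at the last row of the last
#'   column).
#' @param insertion_angle degrees (intramuscular only).
#' @param sampling_rate default sampling rate for recordings made with this
#'   array, Hz (2048 surface, 10240 intramuscular).
#' @return An object of class `electrode_array`.
#' @export
electrode_array <- function(kind = c("surface_grid", "intramuscular_array"),
                            n_rows = NULL, n_cols = NULL,
                            inter_electrode_distance = NULL,
                            missing_electrodes = NULL,
                            insertion_angle = 30,
                            sampling_rate = NULL) {
  kind <- match.arg(kind)
  if (kind == "surface_grid") {
    n_rows <- n_rows %||% 13L
    n_cols <- n_cols %||% 5L
    inter_electrode_distance <- inter_electrode_distance %||% 4
    if (is.null(missing_electrodes) && n_rows == 13L && n_cols == 5L)
      missing_electrodes <- n_rows * n_cols  # one corner absent: 64 active
    sampling_rate <- sampling_rate %||% 2048
  } else {
    n_rows <- n_rows %||% 16L
    n_cols <- 1L
    inter_electrode_distance <- inter_electrode_distance %||% 1
    sampling_rate <- sampling_rate %||% 10240
  }
  n_pos <- n_rows * n_cols
  missing_electrodes <- as.integer(missing_electrodes %||% integer(0))
  if (length(missing_electrodes) &&
      (any(missing_electrodes < 1L) || any(missing_electrodes > n_pos)))
    abort("missing_electrodes out of range", class = "mudecomp_invalid_argument")
  structure(list(kind = kind, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 inter_electrode_distance = inter_electrode_distance,
                 missing_electrodes = missing_electrodes,
                 insertion_angle = insertion_angle,
                 sampling_rate = sampling_rate,
                 n_channels = n_pos - length(missing_electrodes)),
            class = "electrode_array")
}

# 3D positions (x transverse, y depth from muscle axis, z longitudinal; mm) of
# the *active* electrodes of an array over/inside the given anatomy.
array_positions <- function(array, anatomy) {
  stopifnot(inherits(array, "electrode_array"), inherits(anatomy, "muscle_anatomy"))
  ied <- array$inter_electrode_distance
  if (array$kind == "surface_grid") {
    y <- anatomy$muscle_radius + anatomy$subcutaneous_thickness + anatomy$skin_thickness
    # column-major ordering (down each column), grid centred on the muscle
    idx <- seq_len(array$n_rows * array$n_cols)
    col <- (idx - 1L) %/% array$n_rows + 1L
    row <- (idx - 1L) %% array$n_rows + 1L
    pos <- cbind(x = (col - (array$n_cols + 1) / 2) * ied,
                 y = rep(y, length(idx)),
                 z = (row - (array$n_rows + 1) / 2) * ied)
  } else {
    a <- array$insertion_angle * pi / 180
    k <- seq_len(array$n_rows)
    depth0 <- anatomy$muscle_radius * 0.95
    pos <- cbind(x = rep(0, length(k)),
                 y = depth0 - (k - 1) * ied * sin(a),
                 z = (k - (array$n_rows + 1) / 2) * ied * cos(a))
    if (any(abs(pos[, "y"]) >= anatomy$muscle_radius) || any(pos[, "y"] < -anatomy$muscle_radius))
      abort("intramuscular electrode outside the muscle volume",
            class = "mudecomp_invalid_geometry")
  }
  if (length(array$missing_electrodes))
    pos <- pos[-array$missing_electrodes, , drop = FALSE]
  rownames(pos) <- NULL
  pos
}
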