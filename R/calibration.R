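#' Reference saline buffers
#'
#' The conversion from conductance to conductivity is calibrated against a
#' saline buffer of known conductivity whose spectrum is physically flat
#' across the sweep, so that any frequency dependence in its *measured*
#' spectrum is attributable to the instrument (stray capacitance, lead
#' inductance, cell geometry). The default catalogue holds the three buffers
#' used in the liver study: 0.062, 0.13 and 0.25 S/m at 20 degrees C. The
#' 0.25 S/m buffer ("Reference #3") is the default calibration buffer: its
#' impedance is closest to the tissue low-frequency impedance.
#'
#' @param name buffer label.
#' @param sigma_ref known buffer conductivity, S/m (> 0).
#' @param spectrum measured [impedance_spectrum()] of the buffer.
#' @param temperature_c reporting temperature, degrees C.
#' @return `reference_buffer()`: a list with class `reference_buffer`.
#'   `default_buffer_catalogue()`: named numeric vector of conductivities,
#'   S/m at 20 degrees C.
#' @export
reference_buffer <- function(name, sigma_ref, spectrum, temperature_c = 20) {
  if (!is.numeric(sigma_ref) || length(sigma_ref) != 1L || !is.finite(sigma_ref) ||
      sigma_ref <= 0)
    stop_config("buffer '%s': sigma_ref must be a single positive number", name)
  if (!inherits(spectrum, "impedance_spectrum"))
    stop_data("buffer '%s': spectrum must be an impedance_spectrum", name)
  structure(list(name = as.character(name), sigma_ref = sigma_ref,
                 temperature_c = temperature_c, spectrum = spectrum),
            class = "reference_buffer")
}

#' @rdname reference_buffer
#' @export
default_buffer_catalogue <- function() {
  c("Reference #1" = 0.062, "Reference #2" = 0.13, "Reference #3" = 0.25)
}

#' Build a per-frequency calibration curve from a reference buffer
#'
#' The conversion factor is defined per frequency as
#' \deqn{k(f) = \sigma_{ref} / G_{buffer}(f)}
#' where G is the conductance of the measured buffer spectrum. Because the
#' buffer's true conductivity is frequency independent, k(f) absorbs both the
#' probe's cell constant and the instrument's frequency response, so applying
#' it to a tissue measured on the same sweep cancels the common distortion.
#'
#' @param buffer a [reference_buffer()].
#' @return list with class `calibration_curve`: `frequency` (Hz), `k`
#'   (conversion factor, 1/m), `source_buffer`, `sigma_ref`.
#' @export
build_calibration <- function(buffer) {
  if (!inherits(buffer, "reference_buffer"))
    stop_config("build_calibration() needs a reference_buffer")
  g <- conductance(buffer$spectrum)
  if (any(g <= 0))
    stop_data("degenerate buffer '%s': non-positive conductance at %g Hz",
              buffer$name, buffer$spectrum$frequency[which(g <= 0)[1L]])
  k <- buffer$sigma_ref / g
  structure(list(frequency = buffer$spectrum$frequency, k = k,
                 source_buffer = buffer$name, sigma_ref = buffer$sigma_ref),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve from %s (%.3g S/m): %d frequencies, k in [%.4g, %.4g] 1/m\n",
              x$source_buffer, x$sigma_ref, length(x$k), min(x$k), max(x$k)))
  invisible(x)
}

#' Convert a tissue impedance spectrum to conductivity
#'
#' Applies \eqn{\sigma(f) = k(f) \cdot G_{tissue}(f)} with G the conductance
#' of the tissue spectrum. The tissue must have been measured on the same
#' frequency sweep as the calibration buffer; mismatched grids are an error,
#' never interpolated.
#'
#' @param curve a `calibration_curve` from [build_calibration()].
#' @param tissue an [impedance_spectrum()].
#' @param grid_tolerance_rel per-point relative tolerance for grid identity.
#' @return a [conductivity_spectrum()].
#' @export
apply_calibration <- function(curve, tissue, grid_tolerance_rel = 1e-9) {
  if (!inherits(curve, "calibration_curve"))
    stop_config("apply_calibration() needs a calibration_curve")
  stopifnot(inherits(tissue, "impedance_spectrum"))
  if (!same_grid(curve$frequency, tissue$frequency, grid_tolerance_rel))
    stop_data("grid mismatch between calibration curve (%d pts) and tissue (%d pts); no interpolation is performed",
              length(curve$frequency), nrow(tissue))
  sigma <- curve$k * conductance(tissue)
  if (any(sigma <= 0))
    stop_data("calibrated conductivity is non-positive at %g Hz (unusable record)",
              tissue$frequency[which(sigma <= 0)[1L]])
  conductivity_spectrum(tissue$frequency, sigma)
}

#' Calibrate every record of a cohort
#'
#' Replaces each record's impedance spectrum with its calibrated conductivity
#' spectrum, leaving metadata untouched. Records whose spectra are unusable
#' (singular impedance, grid mismatch, non-positive conductivity) are dropped
#' and logged with a reason, never imputed - mirroring the exclusion of
#' technically invalid clinical records.
#'
#' @param cohort list of [measurement_record()]s carrying impedance spectra.
#' @param buffer the [reference_buffer()] used for calibration.
#' @param grid_tolerance_rel see [apply_calibration()].
#' @return cohort of calibrated records; excluded records are reported in
#'   attribute `"exclusions"` (data frame patient_id / tissue_class / state /
#'   reason).
#' @export
calibrate_cohort <- function(cohort, buffer, grid_tolerance_rel = 1e-9) {
  if (!length(cohort)) stop_data("empty cohort")
  curve <- build_calibration(buffer)
  out <- list()
  excl <- list()
  for (rec in cohort) {
    res <- tryCatch(apply_calibration(curve, rec$spectrum, grid_tolerance_rel),
                    error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        patient_id = rec$patient_id, tissue_class = rec$tissue_class,
        state = rec$state, reason = conditionMessage(res))
    } else {
      rec$spectrum <- res
      out[[length(out) + 1L]] <- rec
    }
  }
  if (!length(out))
    stop_data("calibration excluded every record in the cohort")
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(patient_id = character(), tissue_class = character(),
               state = character(), reason = character())
  structure(out, class = "tetracond_cohort", exclusions = exclusions)
}

#' Serialize a calibration curve to CSV
#'
#' Columns `frequency_hz`, `k_per_m`, `source_buffer`.
#'
#' @param curve a `calibration_curve`.
#' @param path output file.
#' @export
write_calibration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  utils::write.csv(data.frame(
    frequency_hz = format(curve$frequency, digits = 15, trim = TRUE),
    k_per_m = format(curve$k, digits = 15, trim = TRUE),
    source_buffer = curve$source_buffer
  ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
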