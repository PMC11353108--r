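#' Measurement records and cohorts
#'
#' A measurement record ties one spectrum (impedance before calibration,
#' conductivity after) to the clinical metadata of the sampled tissue:
#' patient label, tissue class (normal / tumor / cirrhotic), state (in vivo /
#' ex vivo), tumor type (HCC / MET / CCA, or none for non-tumor tissue),
#' optional tumor dimensions in mm and optional temperature in degrees C.
#' Temperature is metadata only; no conductivity-temperature correction is
#' applied by default.
#'
#' @param patient_id patient label.
#' @param tissue_class one of `"normal"`, `"tumor"`, `"cirrhotic"`.
#' @param state one of `"in_vivo"`, `"ex_vivo"`.
#' @param tumor_type one of `"HCC"`, `"MET"`, `"CCA"`, `"none"`. Must be
#'   `"none"` exactly when `tissue_class != "tumor"`.
#' @param spectrum an [impedance_spectrum()] or [conductivity_spectrum()].
#' @param tumor_dims_mm numeric vector of up to three tumor dimensions, mm;
#'   only allowed for tumor tissue.
#' @param temperature_c tissue temperature, degrees C, optional.
#' @return a list with class `measurement_record`.
#' @export
measurement_record <- function(patient_id, tissue_class, state, tumor_type,
                               spectrum, tumor_dims_mm = NULL,
                               temperature_c = NA_real_) {
  tissue_class <- match.arg(tissue_class, c("normal", "tumor", "cirrhotic"))
  state <- match.arg(state, c("in_vivo", "ex_vivo"))
  tumor_type <- match.arg(tumor_type, c("HCC", "MET", "CCA", "none"))
  if ((tissue_class == "tumor") == (tumor_type == "none"))
    stop_data("record '%s': tumor_type must be 'none' iff tissue_class is not 'tumor'",
              patient_id)
  if (!is.null(tumor_dims_mm)) {
    if (tissue_class != "tumor")
      stop_data("record '%s': tumor_dims_mm only allowed for tumor tissue", patient_id)
    tumor_dims_mm <- as.numeric(tumor_dims_mm)
    if (length(tumor_dims_mm) < 1L || length(tumor_dims_mm) > 3L ||
        anyNA(tumor_dims_mm) || any(tumor_dims_mm <= 0))
      stop_data("record '%s': tumor_dims_mm must be 1-3 positive lengths", patient_id)
  }
  if (!inherits(spectrum, "impedance_spectrum") &&
      !inherits(spectrum, "conductivity_spectrum"))
    stop_data("record '%s': spectrum must be an impedance or conductivity spectrum",
              patient_id)
  structure(list(
    patient_id = as.character(patient_id),
    tissue_class = tissue_class,
    state = state,
    tumor_type = tumor_type,
    tumor_dims_mm = tumor_dims_mm,
    temperature_c = as.numeric(temperature_c),
    spectrum = spectrum
  ), class = "measurement_record")
}

#' @param records list of `measurement_record` objects.
#' @rdname measurement_record
#' @export
as_cohort <- function(records) {
  if (!length(records)) stop_data("a cohort must contain at least one record")
  if (!all(vapply(records, inherits, logical(1), "measurement_record")))
    stop_data("all cohort elements must be measurement_record objects")
  structure(records, class = "tetracond_cohort")
}

#' @export
print.measurement_record <- function(x, ...) {
  kind <- if (inherits(x$spectrum, "conductivity_spectrum")) "conductivity" else "impedance"
  cat(sprintf("Record %s: %s %s%s, %s spectrum (%d freqs)\n",
              x$patient_id, gsub("_", " ", x$state), x$tissue_class,
              if (x$tumor_type != "none") paste0(" (", x$tumor_type, ")") else "",
              kind, nrow(x$spectrum)))
  invisible(x)
}

#' @export
print.tetracond_cohort <- function(x, ...) {
  cls <- table(vapply(x, function(r) paste(r$state, r$tissue_class), ""))
  cat(sprintf("Cohort of %d records:\n", length(x)))
  for (nm in names(cls)) cat(sprintf("  %-22s %d\n", nm, cls[[nm]]))
  invisible(x)
}

#' Cohort metadata as a data frame
#'
#' One row per record: patient, tissue class, state, tumor type, dimensions
#' (formatted `"a x b x c"`), temperature.
#'
#' @param cohort a cohort (list of records).
#' @return data frame, one row per record.
#' @export
cohort_metadata <- function(cohort) {
  do.call(rbind, lapply(cohort, function(r) {
    data.frame(
      patient_id = r$patient_id,
      tissue_class = r$tissue_class,
      state = r$state,
      tumor_type = r$tumor_type,
      tumor_dims_mm = if (is.null(r$tumor_dims_mm)) NA_character_ else
        paste(format(r$tumor_dims_mm, trim = TRUE), collapse = " x "),
      temperature_c = r$temperature_c
    )
  }))
}
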