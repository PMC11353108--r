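# CSV layer. Dialect: comma-separated, mandatory header, '.' decimal, UTF-8.
# Values are written with 15 significant digits so read-backs agree to at
# least 12 significant digits.

.num_col <- function(raw, col, path) {
  v <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.finite(v))
  if (length(bad))
    stop_data("parse error in '%s': non-numeric or non-finite value '%s' in column '%s' at data row %d",
              path, raw[bad[1L]], col, bad[1L])
  v
}

.require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_data("'%s' is missing required column(s): %s",
              path, paste(missing, collapse = ", "))
}

#' Read an impedance spectrum from CSV
#'
#' Expects columns `frequency_hz`, `resistance_ohm`, `reactance_ohm`. Rows may
#' appear in any order; the returned spectrum is sorted by frequency.
#' Duplicate frequencies and non-numeric cells are rejected (never averaged
#' or imputed): they indicate acquisition faults.
#'
#' @param path CSV file path.
#' @return an [impedance_spectrum()].
#' @export
read_impedance_csv <- function(path) {
  if (!file.exists(path)) stop_data("file not found: '%s'", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  .require_cols(df, c("frequency_hz", "resistance_ohm", "reactance_ohm"), path)
  f <- .num_col(df$frequency_hz, "frequency_hz", path)
  r <- .num_col(df$resistance_ohm, "resistance_ohm", path)
  x <- .num_col(df$reactance_ohm, "reactance_ohm", path)
  dup <- which(duplicated(f))
  if (length(dup))
    stop_data("parse error in '%s': duplicate frequency %g Hz at data row %d",
              path, f[dup[1L]], dup[1L])
  o <- order(f)
  impedance_spectrum(f[o], r[o], x[o])
}

#' @param z an [impedance_spectrum()] to write.
#' @rdname read_impedance_csv
#' @export
write_impedance_csv <- function(z, path) {
  stopifnot(inherits(z, "impedance_spectrum"))
  df <- data.frame(frequency_hz = format(z$frequency, digits = 15, trim = TRUE),
                   resistance_ohm = format(z$resistance, digits = 15, trim = TRUE),
                   reactance_ohm = format(z$reactance, digits = 15, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a conductivity spectrum as CSV
#'
#' Columns `frequency_hz`, `conductivity_s_per_m`. Round-trips are lossless to
#' at least 12 significant digits.
#'
#' @param spec a [conductivity_spectrum()].
#' @param path CSV file path.
#' @return `write_conductivity_csv()` invisibly returns `path`;
#'   `read_conductivity_csv()` returns a [conductivity_spectrum()].
#' @export
write_conductivity_csv <- function(spec, path) {
  if (!inherits(spec, "conductivity_spectrum"))
    stop_data("'spec' must be a conductivity_spectrum")
  df <- data.frame(
    frequency_hz = format(spec$frequency, digits = 15, trim = TRUE),
    conductivity_s_per_m = format(spec$sigma, digits = 15, trim = TRUE)
  )
  ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_data("cannot write conductivity CSV to '%s'", path)
  invisible(path)
}

#' @rdname write_conductivity_csv
#' @export
read_conductivity_csv <- function(path) {
  if (!file.exists(path)) stop_data("file not found: '%s'", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  .require_cols(df, c("frequency_hz", "conductivity_s_per_m"), path)
  f <- .num_col(df$frequency_hz, "frequency_hz", path)
  s <- .num_col(df$conductivity_s_per_m, "conductivity_s_per_m", path)
  o <- order(f)
  conductivity_spectrum(f[o], s[o])
}
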