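#' Impedance and conductivity spectra
#'
#' An impedance spectrum holds the per-frequency real part R (ohm) and
#' imaginary part X (ohm) of the complex impedance Z = R + iX measured by a
#' tetrapolar probe. X is stored signed (capacitive behaviour gives X < 0);
#' the conductance formula uses X^2 so the sign convention only matters for
#' phase plots. A conductivity spectrum holds the tissue conductivity sigma
#' (S/m) per frequency.
#'
#' Invariants enforced: R >= 0 everywhere (passive system), at least one
#' frequency with |Z| > 0, and (for conductivity) sigma finite and > 0.
#'
#' @param frequency frequencies, Hz (strictly increasing, > 0).
#' @param resistance per-frequency real part of Z, ohm.
#' @param reactance per-frequency imaginary part of Z, ohm.
#' @return `impedance_spectrum()` returns a data frame with columns
#'   `frequency`, `resistance`, `reactance` and class `impedance_spectrum`;
#'   `conductivity_spectrum()` a data frame with `frequency`, `sigma` and
#'   class `conductivity_spectrum`.
#' @examples
#' z <- impedance_spectrum(c(1e3, 1e4), resistance = c(100, 90),
#'                         reactance = c(-5, -20))
#' conductance(z)
#' @export
impedance_spectrum <- function(frequency, resistance, reactance) {
  f <- validate_frequency_grid(frequency)
  r <- as.numeric(resistance)
  x <- as.numeric(reactance)
  if (length(r) != length(f) || length(x) != length(f))
    stop_data("resistance and reactance must match the grid length (%d)", length(f))
  if (anyNA(r) || anyNA(x) || any(!is.finite(r)) || any(!is.finite(x)))
    stop_data("resistance and reactance must be finite and non-missing")
  if (any(r < 0))
    stop_data("negative resistance at %g Hz: a passive system requires R >= 0",
              f[which(r < 0)[1L]])
  if (all(r == 0 & x == 0))
    stop_data("degenerate spectrum: R and X are zero at every frequency")
  structure(
    data.frame(frequency = as.numeric(f), resistance = r, reactance = x),
    class = c("impedance_spectrum", "data.frame")
  )
}

#' @param sigma per-frequency conductivity, S/m (finite, > 0).
#' @rdname impedance_spectrum
#' @export
conductivity_spectrum <- function(frequency, sigma) {
  f <- validate_frequency_grid(frequency)
  s <- as.numeric(sigma)
  if (length(s) != length(f))
    stop_data("sigma must match the grid length (%d)", length(f))
  if (anyNA(s) || any(!is.finite(s)) || any(s <= 0))
    stop_data("conductivity must be finite and > 0 at every frequency")
  structure(
    data.frame(frequency = as.numeric(f), sigma = s),
    class = c("conductivity_spectrum", "data.frame")
  )
}

#' Conductance from a complex impedance spectrum
#'
#' The conductance is the real part of the admittance Y = 1/Z:
#' G(f) = R / (R^2 + X^2), in siemens. This is the quantity the buffer
#' calibration converts into conductivity.
#'
#' @param z an `impedance_spectrum`.
#' @return numeric vector of conductances, S, one per frequency.
#' @export
conductance <- function(z) {
  stopifnot(inherits(z, "impedance_spectrum"))
  denom <- z$resistance^2 + z$reactance^2
  if (any(denom == 0))
    stop_data("singular impedance (R = X = 0) at %g Hz",
              z$frequency[which(denom == 0)[1L]])
  z$resistance / denom
}

#' Magnitude and phase of an impedance spectrum
#'
#' @param z an `impedance_spectrum`.
#' @return data frame with `frequency` (Hz), `magnitude` (ohm) and `phase_deg`
#'   (degrees, in (-180, 180], from atan2(X, R)).
#' @export
magnitude_phase <- function(z) {
  stopifnot(inherits(z, "impedance_spectrum"))
  data.frame(
    frequency = z$frequency,
    magnitude = sqrt(z$resistance^2 + z$reactance^2),
    phase_deg = atan2(z$reactance, z$resistance) * 180 / pi
  )
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum: %d frequencies, %.4g Hz - %.4g Hz\n",
              nrow(x), min(x$frequency), max(x$frequency)))
  NextMethod()
}

#' @export
print.conductivity_spectrum <- function(x, ...) {
  cat(sprintf("Conductivity spectrum: %d frequencies, %.4g Hz - %.4g Hz\n",
              nrow(x), min(x$frequency), max(x$frequency)))
  NextMethod()
}
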