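#' Cole dispersion model of tissue impedance
#'
#' Tissue impedance across the beta-dispersion band is emulated with the
#' standard Cole model
#' \deqn{Z(f) = R_\infty + (R_0 - R_\infty) / (1 + (i f / f_c)^\alpha)}
#' with zero-frequency resistance R0, infinite-frequency resistance R_inf,
#' characteristic frequency fc and broadness alpha in (0, 1]. With
#' R0 > R_inf the derived conductance (and hence conductivity) rises
#' monotonically with frequency, the pattern seen in liver tissue.
#'
#' @param r0 zero-frequency resistance, ohm.
#' @param r_inf infinite-frequency resistance, ohm (0 < r_inf < r0).
#' @param fc characteristic frequency, Hz.
#' @param alpha dispersion broadness, in (0, 1].
#' @return `cole_parameters()`: list with class `cole_parameters`.
#' @export
cole_parameters <- function(r0, r_inf, fc, alpha = 1) {
  if (!all(is.finite(c(r0, r_inf, fc, alpha))))
    stop_config("Cole parameters must be finite")
  if (!(r0 > r_inf && r_inf > 0))
    stop_config("Cole parameters require r0 > r_inf > 0 (got r0=%g, r_inf=%g)", r0, r_inf)
  if (fc <= 0) stop_config("Cole fc must be > 0")
  if (alpha <= 0 || alpha > 1) stop_config("Cole alpha must be in (0, 1]")
  structure(list(r0 = r0, r_inf = r_inf, fc = fc, alpha = alpha),
            class = "cole_parameters")
}

# Complex Cole impedance on a frequency vector (internal workhorse).
cole_z <- function(p, frequency) {
  jw <- (1i * frequency / p$fc)^p$alpha
  p$r_inf + (p$r0 - p$r_inf) / (1 + jw)
}

#' @param p a `cole_parameters` object.
#' @param grid frequency vector, Hz.
#' @return `cole_impedance()`: an [impedance_spectrum()] of the model
#'   evaluated on the grid.
#' @rdname cole_parameters
#' @export
cole_impedance <- function(p, grid = default_frequency_grid()) {
  stopifnot(inherits(p, "cole_parameters"))
  z <- cole_z(p, as.numeric(grid))
  impedance_spectrum(grid, Re(z), Im(z))
}

#' Probe geometry of the in-line four-needle electrode array
#'
#' Defaults describe the array used in the liver study: needles of 0.35 mm
#' outer diameter (radius 0.175 mm), 1 mm apart, last 3 mm of the tip
#' electrically active, the four in-line electrodes spanning 3 mm. The cell
#' constant kappa (1/m) relates conductance to conductivity for an ideal
#' (distortion-free) measurement, sigma = kappa * G; its default of 25 1/m is
#' an order-of-magnitude value for millimetre-spaced needle tetrapoles.
#'
#' @param needle_radius_mm electrode radius, mm.
#' @param needle_spacing_mm inter-electrode distance, mm.
#' @param active_tip_mm electrically active tip length, mm.
#' @param array_span_mm length taken up by the four in-line electrodes, mm.
#' @param cell_constant_per_m kappa, 1/m.
#' @return list with class `probe_geometry`.
#' @export
probe_geometry <- function(needle_radius_mm = 0.175, needle_spacing_mm = 1.0,
                           active_tip_mm = 3.0, array_span_mm = 3.0,
                           cell_constant_per_m = 25) {
  v <- c(needle_radius_mm, needle_spacing_mm, active_tip_mm, array_span_mm,
         cell_constant_per_m)
  if (!all(is.finite(v)) || any(v <= 0))
    stop_config("all probe geometry values must be positive and finite")
  structure(list(needle_radius_mm = needle_radius_mm,
                 needle_spacing_mm = needle_spacing_mm,
                 active_tip_mm = active_tip_mm,
                 array_span_mm = array_span_mm,
                 cell_constant_per_m = cell_constant_per_m),
            class = "probe_geometry")
}

#' Ideal impedance spectrum of a resistive reference buffer
#'
#' A saline buffer is purely resistive and frequency-flat: R(f) =
#' kappa / sigma at every frequency, X(f) = 0. Instrument distortion is added
#' separately with [apply_parasitics()].
#'
#' @param sigma buffer conductivity, S/m (> 0).
#' @param geometry a [probe_geometry()] supplying the cell constant.
#' @param grid frequency vector, Hz.
#' @return an [impedance_spectrum()].
#' @export
buffer_impedance <- function(sigma, geometry = probe_geometry(),
                             grid = default_frequency_grid()) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop_config("buffer sigma must be a single positive number")
  stopifnot(inherits(geometry, "probe_geometry"))
  f <- as.numeric(grid)
  r <- geometry$cell_constant_per_m / sigma
  impedance_spectrum(f, rep(r, length(f)), rep(0, length(f)))
}

#' Instrument parasitics: lead inductance and stray capacitance
#'
#' The minimal two-element network reproducing the high-frequency artefacts
#' of a swept bioimpedance analyser: a series lead inductance L and a stray
#' capacitance C in parallel with the device under test,
#' \deqn{Z_{meas}(f) = i\omega L + \frac{Z(f)}{1 + i\omega C\, Z(f)}, \quad \omega = 2\pi f.}
#' Defaults (L = 0.5 uH, C = 0.5 nF) make the distortion material (> 5 % of
#' |Z|) at 1 MHz and negligible at 3 kHz for tissue-like impedances.
#' `parasitic_model(0, 0)` is the ideal instrument.
#'
#' @param l_series_h lead inductance, H (>= 0).
#' @param c_parallel_f stray capacitance, F (>= 0).
#' @return `parasitic_model()`: list with class `parasitic_model`.
#' @export
parasitic_model <- function(l_series_h = 0.5e-6, c_parallel_f = 0.5e-9) {
  if (!all(is.finite(c(l_series_h, c_parallel_f))) ||
      l_series_h < 0 || c_parallel_f < 0)
    stop_config("parasitic L and C must be finite and >= 0")
  structure(list(l_series_h = l_series_h, c_parallel_f = c_parallel_f),
            class = "parasitic_model")
}

#' @param z an [impedance_spectrum()] of the device under test.
#' @param par a `parasitic_model`.
#' @return `apply_parasitics()`: the distorted [impedance_spectrum()].
#' @rdname parasitic_model
#' @export
apply_parasitics <- function(z, par = parasitic_model()) {
  stopifnot(inherits(z, "impedance_spectrum"), inherits(par, "parasitic_model"))
  if (par$l_series_h == 0 && par$c_parallel_f == 0) return(z)
  w <- 2 * pi * z$frequency
  zc <- complex(real = z$resistance, imaginary = z$reactance)
  zm <- 1i * w * par$l_series_h + zc / (1 + 1i * w * par$c_parallel_f * zc)
  impedance_spectrum(z$frequency, Re(zm), Im(zm))
}
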