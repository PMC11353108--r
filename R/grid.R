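#' Frequency grids for impedance sweeps
#'
#' A frequency grid is a strictly increasing numeric vector of frequencies in
#' Hz, all positive. The default grid mirrors a swept-frequency bioimpedance
#' analyser: 256 logarithmically spaced points from 3 kHz to 1 MHz inclusive.
#'
#' @param n number of grid points.
#' @param f_min,f_max grid endpoints, Hz.
#' @return Numeric vector of frequencies in Hz, class `frequency_grid`.
#' @examples
#' g <- default_frequency_grid()
#' length(g)      # 256
#' range(g)       # 3e3 1e6
#' @export
log_frequency_grid <- function(n = 256, f_min = 3e3, f_max = 1e6) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop_config("grid size 'n' must be a single integer >= 2")
  if (f_min <= 0 || f_max <= f_min)
    stop_config("grid endpoints must satisfy 0 < f_min < f_max")
  f <- exp(seq(log(f_min), log(f_max), length.out = n))
  # pin endpoints exactly: exp/log round-trip can be off in the last ulp
  f[1L] <- f_min
  f[n] <- f_max
  validate_frequency_grid(f)
}

#' @rdname log_frequency_grid
#' @export
default_frequency_grid <- function() log_frequency_grid(256, 3e3, 1e6)

#' @param frequencies numeric vector of frequencies, Hz.
#' @rdname log_frequency_grid
#' @export
validate_frequency_grid <- function(frequencies) {
  f <- as.numeric(frequencies)
  if (length(f) < 1L || anyNA(f) || any(!is.finite(f)))
    stop_data("frequency grid must be non-empty, finite and non-missing")
  if (any(f <= 0))
    stop_data("frequency grid must be strictly positive")
  if (is.unsorted(f, strictly = TRUE))
    stop_data("frequency grid must be strictly increasing (duplicates are rejected)")
  structure(f, class = "frequency_grid")
}

#' Compare two grids for alignment
#'
#' Calibration curves may only be applied to spectra sharing the grid they
#' were built on; no interpolation is ever performed (it would silently bend
#' the conversion factor where the parasitic distortion is steep).
#'
#' @param a,b frequency vectors, Hz.
#' @param tol_rel relative tolerance per point.
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol_rel = 1e-9) {
  a <- as.numeric(a); b <- as.numeric(b)
  length(a) == length(b) && all(abs(a - b) <= tol_rel * pmax(abs(a), abs(b)))
}
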