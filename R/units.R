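# Unit conversions between user-facing prior-knowledge units
# (ppm, Hz FWHM, degrees) and the internal model parameterisation
# (Hz, damping s^-1, radians).

#' Convert a chemical shift to a model frequency
#'
#' The model works with frequencies in Hz relative to the receiver centre;
#' prior knowledge is expressed in field-independent ppm. The convention is
#' `f[Hz] = (shift[ppm] - reference_shift[ppm]) * transmitter_freq[MHz]`,
#' so a positive ppm offset maps to a positive Hz offset.
#'
#' @param shift_ppm Chemical shift(s) in ppm.
#' @param transmitter_freq Transmitter (Larmor) frequency in MHz.
#' @param reference_shift Chemical shift in ppm that maps to 0 Hz.
#' @return Frequency in Hz.
#' @export
ppm_to_hz <- function(shift_ppm, transmitter_freq, reference_shift = 0) {
  (shift_ppm - reference_shift) * transmitter_freq
}

#' @rdname ppm_to_hz
#' @param freq_hz Frequency in Hz.
#' @export
hz_to_ppm <- function(freq_hz, transmitter_freq, reference_shift = 0) {
  freq_hz / transmitter_freq + reference_shift
}

#' Convert spectral linewidth (FWHM, Hz) to the model damping factor
#'
#' For a Lorentzian peak (`g = 0`, exponential decay `exp(-d t)`) the
#' full width at half maximum is `d / pi`; for a Gaussian peak (`g = 1`,
#' decay `exp(-d t^2)`) it is `2 sqrt(d log 2) / pi`. For intermediate
#' lineshapes the damping is interpolated linearly in `g` between the two
#' pure conversions,
#' `d = (1 - g) * pi * lw + g * (pi * lw)^2 / (4 log 2)`,
#' which is exact at both endpoints and smooth in `g` and `lw`.
#'
#' @param lw Linewidth (full width at half maximum) in Hz.
#' @param g Lineshape parameter in `[0, 1]`: 0 Lorentzian, 1 Gaussian.
#' @return Damping factor in s^-1 (`g = 0`) or s^-2 (`g = 1`).
#' @export
lw_to_damping <- function(lw, g = 0) {
  (1 - g) * pi * lw + g * (pi * lw)^2 / (4 * log(2))
}

#' @rdname lw_to_damping
#' @param d Damping factor as used by the model.
#' @export
damping_to_lw <- function(d, g = 0) {
  n <- max(length(d), length(g))
  d <- rep_len(d, n); g <- rep_len(g, n)
  a <- g * pi^2 / (4 * log(2))
  b <- (1 - g) * pi
  out <- d / pi
  pos <- a > 0
  out[pos] <- (-b[pos] + sqrt(b[pos]^2 + 4 * a[pos] * d[pos])) / (2 * a[pos])
  out
}

# d(damping)/d(linewidth): chain-rule factor for constraint Jacobians.
lw_to_damping_grad <- function(lw, g = 0) {
  (1 - g) * pi + g * pi^2 * lw / (2 * log(2))
}

deg_to_rad <- function(x) x * pi / 180
rad_to_deg <- function(x) x * 180 / pi

# Wrap phases (degrees) into [lower, upper] by adding multiples of 360
# where possible, clipping otherwise.
wrap_phase_deg <- function(x, lower = -180, upper = 180) {
  wrapped <- x - 360 * ceiling((x - upper) / 360)
  pmin(pmax(wrapped, lower), upper)
}
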