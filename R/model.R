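#' Sinusoid parameter table (internal model units)
#'
#' The forward model is a sum of `K` exponentially damped sinusoids
#' evaluated on the FID time axis `t_n = n * dwell_time + dead_time`:
#'
#' `yhat_n = sum_k a_k exp(i phi_k) exp(-d_k (1 - g_k + g_k t_n) t_n) exp(i 2 pi f_k t_n)`
#'
#' so each peak decays exponentially (`g_k = 0`, Lorentzian line), as a
#' Gaussian (`g_k = 1`), or in between. This constructor holds parameters
#' in the model's internal units: phase in radians, damping in s^-1
#' (Lorentzian part), frequency in Hz. User-facing interfaces (prior
#' knowledge, fit results, files) use degrees, Hz FWHM and ppm instead.
#'
#' @param amplitude Amplitudes `a_k >= 0` (signal units).
#' @param phase Phases `phi_k` in radians.
#' @param damping Damping factors `d_k >= 0`.
#' @param frequency Frequencies `f_k` in Hz.
#' @param lineshape_g Lineshape parameters `g_k` in `[0, 1]`.
#' @return A tibble with one row per sinusoid.
#' @export
sinusoids <- function(amplitude, phase = 0, damping = 0, frequency = 0,
                      lineshape_g = 0) {
  out <- tibble(amplitude = as.numeric(amplitude),
                phase = as.numeric(phase),
                damping = as.numeric(damping),
                frequency = as.numeric(frequency),
                lineshape_g = as.numeric(lineshape_g))
  validate_sinusoids(out)
  out
}

validate_sinusoids <- function(peaks) {
  needed <- c("amplitude", "phase", "damping", "frequency", "lineshape_g")
  missing_cols <- setdiff(needed, names(peaks))
  if (length(missing_cols) > 0) {
    abort(paste0("sinusoid table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mrsfit_error_validation")
  }
  vals <- unlist(peaks[needed], use.names = FALSE)
  if (any(!is.finite(vals))) {
    abort("sinusoid parameters must all be finite.",
          class = "mrsfit_error_validation")
  }
  if (any(peaks$damping < 0)) {
    abort("damping factors must be >= 0.", class = "mrsfit_error_validation")
  }
  if (any(peaks$lineshape_g < 0 | peaks$lineshape_g > 1)) {
    abort("lineshape_g must lie in [0, 1].", class = "mrsfit_error_validation")
  }
  invisible(peaks)
}

# Per-peak contribution matrix, N x K complex.
peak_contributions <- function(peaks, fid) {
  t <- fid_time_axis(fid)
  vapply(seq_len(nrow(peaks)), function(k) {
    a <- peaks$amplitude[k]; phi <- peaks$phase[k]
    d <- peaks$damping[k]; f <- peaks$frequency[k]
    g <- peaks$lineshape_g[k]
    a * exp(1i * phi) * exp(-d * (1 - g + g * t) * t) * exp(2i * pi * f * t)
  }, complex(fid$n_points))
}

#' Evaluate the damped-sinusoid forward model
#'
#' @param peaks Sinusoid table from [sinusoids()] (internal units).
#' @param fid A [fid_series()] or [fid_meta()] supplying the time axis.
#' @return Complex vector of length `fid$n_points`.
#' @examples
#' meta <- fid_meta(256, dwell_time = 1e-3, transmitter_freq = 120.3)
#' y <- evaluate_model(sinusoids(1, damping = 20, frequency = 50), meta)
#' @export
evaluate_model <- function(peaks, fid) {
  validate_sinusoids(peaks)
  stopifnot(inherits(fid, "fid_series"))
  if (nrow(peaks) == 0) {
    return(complex(fid$n_points))
  }
  contrib <- peak_contributions(peaks, fid)
  # left-to-right summation keeps the model exactly additive over peaks
  out <- contrib[, 1]
  for (k in seq_len(ncol(contrib))[-1]) out <- out + contrib[, k]
  out
}

#' Analytic Jacobian of the forward model
#'
#' Columns are the partial derivatives of the model with respect to each
#' sinusoid's parameters in the fixed order amplitude, phase, damping,
#' frequency (4 columns per sinusoid, peaks in row order of `peaks`), i.e.
#' column `4(k-1) + j` is the derivative for peak `k`, parameter `j`.
#' The lineshape `g_k` is prior knowledge, not a model parameter, so it has
#' no column.
#'
#' @inheritParams evaluate_model
#' @return Complex matrix, `fid$n_points` x `4 * nrow(peaks)`.
#' @export
model_jacobian <- function(peaks, fid) {
  validate_sinusoids(peaks)
  stopifnot(inherits(fid, "fid_series"))
  K <- nrow(peaks)
  t <- fid_time_axis(fid)
  J <- matrix(complex(1), nrow = fid$n_points, ncol = 4 * K)
  if (K == 0) return(J[, 0, drop = FALSE])
  contrib <- peak_contributions(peaks, fid)
  for (k in seq_len(K)) {
    a <- peaks$amplitude[k]; g <- peaks$lineshape_g[k]
    ck <- contrib[, k]
    base <- 4 * (k - 1)
    # d/da: contribution at unit amplitude (valid also when a = 0)
    if (a != 0) {
      J[, base + 1] <- ck / a
    } else {
      unit <- peaks[k, ]; unit$amplitude <- 1
      J[, base + 1] <- peak_contributions(unit, fid)[, 1]
    }
    J[, base + 2] <- 1i * ck
    J[, base + 3] <- -(1 - g + g * t) * t * ck
    J[, base + 4] <- 2i * pi * t * ck
  }
  J
}
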