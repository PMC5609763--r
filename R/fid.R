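#' Free-induction decay (FID) container
#'
#' Bundles the complex time-domain samples of an MRS acquisition with the
#' metadata needed to fit and display them. The time axis is
#' `t_n = n * dwell_time + dead_time` for `n = 0 ... N-1`, i.e. `dead_time`
#' is the delay between excitation and the first recorded point.
#'
#' @param samples Complex vector of time-domain samples (arbitrary signal
#'   units). May be length zero only when constructing pure metadata via
#'   [fid_meta()].
#' @param dwell_time Sampling interval in seconds (`> 0`).
#' @param dead_time Time before the first data point, in seconds (`>= 0`).
#' @param transmitter_freq Transmitter (Larmor) frequency in MHz.
#' @param reference_shift Chemical shift in ppm mapped to 0 Hz.
#' @param nucleus Label for the observed nucleus, e.g. `"31P"`.
#' @return An object of class `fid_series`.
#' @examples
#' fid <- fid_series(complex(real = rnorm(64), imaginary = rnorm(64)),
#'                   dwell_time = 1e-4, transmitter_freq = 120.3)
#' length(fid$samples)
#' @export
fid_series <- function(samples, dwell_time, dead_time = 0,
                       transmitter_freq, reference_shift = 0,
                       nucleus = "31P") {
  samples <- as.complex(samples)
  if (length(samples) < 1) {
    abort("`samples` must contain at least one point.",
          class = "mrsfit_error_validation")
  }
  meta <- fid_meta(length(samples), dwell_time, dead_time,
                   transmitter_freq, reference_shift, nucleus)
  meta$samples <- samples
  meta
}

#' @rdname fid_series
#' @param n_points Number of samples the acquisition would contain.
#' @export
fid_meta <- function(n_points, dwell_time, dead_time = 0,
                     transmitter_freq, reference_shift = 0,
                     nucleus = "31P") {
  n_points <- as.integer(n_points)
  stop_unless(n_points >= 1, "`n_points` must be >= 1.")
  stop_unless(is.numeric(dwell_time) && length(dwell_time) == 1 &&
                is.finite(dwell_time) && dwell_time > 0,
              "`dwell_time` must be a single positive number (seconds).")
  stop_unless(is.numeric(dead_time) && length(dead_time) == 1 &&
                is.finite(dead_time) && dead_time >= 0,
              "`dead_time` must be a single non-negative number (seconds).")
  stop_unless(is.numeric(transmitter_freq) && length(transmitter_freq) == 1 &&
                is.finite(transmitter_freq) && transmitter_freq > 0,
              "`transmitter_freq` must be a single positive number (MHz).")
  stop_unless(is.numeric(reference_shift) && length(reference_shift) == 1 &&
                is.finite(reference_shift),
              "`reference_shift` must be a single finite number (ppm).")
  structure(
    list(samples = NULL,
         n_points = n_points,
         dwell_time = as.numeric(dwell_time),
         dead_time = as.numeric(dead_time),
         transmitter_freq = as.numeric(transmitter_freq),
         reference_shift = as.numeric(reference_shift),
         nucleus = as.character(nucleus)),
    class = "fid_series"
  )
}

#' @export
print.fid_series <- function(x, ...) {
  cat(sprintf(
    "<fid_series> %d points%s, dwell %.3g us, dead time %.3g us, %s at %.4f MHz (ref %.2f ppm)\n",
    x$n_points,
    if (is.null(x$samples)) " (metadata only)" else "",
    x$dwell_time * 1e6, x$dead_time * 1e6, x$nucleus,
    x$transmitter_freq, x$reference_shift))
  invisible(x)
}

#' Time axis of an FID
#'
#' @param fid A [fid_series()] object.
#' @return Numeric vector of sample times in seconds.
#' @export
fid_time_axis <- function(fid) {
  stopifnot(inherits(fid, "fid_series"))
  (seq_len(fid$n_points) - 1L) * fid$dwell_time + fid$dead_time
}

# internal condition helper
stop_unless <- function(cond, msg, class = "mrsfit_error_validation") {
  if (!isTRUE(cond)) abort(msg, class = class)
  invisible(TRUE)
}
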