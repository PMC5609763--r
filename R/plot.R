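# Static figures: fit overview (time and frequency domain, per-peak
# spectra truncated for display) and CSI amplitude maps.

# Discrete-time Fourier transform of complex samples at arbitrary
# frequencies (Hz), matching the model's exp(+2i pi f t) convention.
dtft_at <- function(samples, t, freqs) {
  vapply(freqs, function(f) sum(samples * exp(-2i * pi * f * t)),
         complex(1)) * (t[2] - t[1])
}

# fftshift-ed frequency axis (Hz) for an N-point FID.
spectrum_freq_axis <- function(fid) {
  N <- fid$n_points
  bw <- 1 / fid$dwell_time
  (seq_len(N) - 1 - floor(N / 2)) * bw / N
}

fid_spectrum <- function(samples, fid) {
  N <- length(samples)
  sp <- fft(samples) * fid$dwell_time
  idx <- c(seq.int(floor(N / 2) + 1, N), seq_len(floor(N / 2)))
  sp[idx]
}

#' Frequency-domain traces of a fit
#'
#' Returns the plotted arrays behind [plot_fit()]: the data, total-model
#' and residual spectra on the acquisition frequency grid, and each
#' fitted peak's spectrum evaluated on a fine grid whose support spans
#' exactly `display_fwhm` times that peak's fitted full width at half
#' maximum, centred on its fitted frequency (a display truncation only —
#' the fit always uses every point).
#'
#' @param fit An [fit_amares()] result.
#' @param display_fwhm Display window width in units of each peak's FWHM.
#' @param n_window Points per peak display window.
#' @return A list of tibbles `spectra` (columns `frequency_hz`,
#'   `shift_ppm`, `trace`, `value`) and `peaks` (columns `component`,
#'   `frequency_hz`, `shift_ppm`, `value`).
#' @export
fit_spectra <- function(fit, display_fwhm = 2.5, n_window = 201) {
  stopifnot(inherits(fit, "amares_fit"))
  fid <- fit$fid
  t <- fid_time_axis(fid)
  freqs <- spectrum_freq_axis(fid)
  model <- evaluate_model(fit$peaks, fid)
  to_ppm <- function(f) hz_to_ppm(f, fid$transmitter_freq, fid$reference_shift)
  spectra <- dplyr::bind_rows(
    tibble(frequency_hz = freqs, trace = "data",
           value = Re(fid_spectrum(fid$samples, fid))),
    tibble(frequency_hz = freqs, trace = "fit",
           value = Re(fid_spectrum(model, fid))),
    tibble(frequency_hz = freqs, trace = "residual",
           value = Re(fid_spectrum(fit$residual, fid))))
  spectra$shift_ppm <- to_ppm(spectra$frequency_hz)

  est <- peak_estimates(fit)
  peaks <- purrr::map_dfr(seq_len(nrow(est)), function(k) {
    fwhm <- damping_to_lw(fit$peaks$damping[k], fit$peaks$lineshape_g[k])
    fk <- fit$peaks$frequency[k]
    fgrid <- seq(fk - display_fwhm / 2 * fwhm, fk + display_fwhm / 2 * fwhm,
                 length.out = n_window)
    tibble(component = est$component[k],
           frequency_hz = fgrid,
           shift_ppm = to_ppm(fgrid),
           value = Re(dtft_at(peak_contributions(fit$peaks[k, ], fid)[, 1],
                              t, fgrid)))
  })
  list(spectra = spectra, peaks = peaks)
}

#' Plot an AMARES fit
#'
#' Renders the frequency-domain data, total fit, residual and individual
#' peak spectra (each truncated to 2.5 times its fitted FWHM for display),
#' plus the time-domain data and fit, as a two-panel figure. The ppm axis
#' is reversed, following spectroscopy convention.
#'
#' @param fit An [fit_amares()] result.
#' @param out_path Optional file path (png/pdf); written with
#'   [ggplot2::ggsave()].
#' @param display_fwhm Per-peak display window in FWHM multiples.
#' @return A list with the ggplot objects `frequency` and `time` and the
#'   [fit_spectra()] arrays, invisibly.
#' @export
plot_fit <- function(fit, out_path = NULL, display_fwhm = 2.5) {
  sp <- fit_spectra(fit, display_fwhm = display_fwhm)
  offset <- 1.1 * max(abs(sp$spectra$value[sp$spectra$trace == "data"]))
  freq_df <- sp$spectra
  freq_df$value[freq_df$trace == "residual"] <-
    freq_df$value[freq_df$trace == "residual"] - offset
  p_freq <- ggplot2::ggplot(freq_df,
                            ggplot2::aes(x = .data$shift_ppm, y = .data$value,
                                         colour = .data$trace)) +
    ggplot2::geom_line(data = sp$peaks,
                       ggplot2::aes(group = .data$component),
                       colour = "grey55", linewidth = 0.3) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "real spectrum (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  t_axis <- fid_time_axis(fit$fid)
  time_df <- dplyr::bind_rows(
    tibble(t = t_axis, trace = "data", value = Re(fit$fid$samples)),
    tibble(t = t_axis, trace = "fit",
           value = Re(evaluate_model(fit$peaks, fit$fid))))
  p_time <- ggplot2::ggplot(time_df,
                            ggplot2::aes(x = .data$t, y = .data$value,
                                         colour = .data$trace)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "Re FID (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    combined <- patchwork::wrap_plots(p_freq, p_time, ncol = 1)
    ggplot2::ggsave(out_path, plot = combined, width = 7, height = 8,
                    dpi = 150)
  }
  invisible(list(frequency = p_freq, time = p_time,
                 spectra = sp$spectra, peaks = sp$peaks))
}

#' @method autoplot amares_fit
#' @export
autoplot.amares_fit <- function(object, ...) {
  plot_fit(object, ...)$frequency
}

#' Plot a fitted amplitude map from a batch result
#'
#' @param table A [batch_fit()] result from a CSI grid.
#' @param peak Component name (e.g. `"PCR"`) whose amplitude to map.
#' @param out_path Optional figure file path.
#' @param slice 1-based slice index (third voxel axis).
#' @return A list with the ggplot object `plot` and the amplitude matrix
#'   `map` (non-converged voxels `NA`/masked), invisibly.
#' @export
plot_amplitude_map <- function(table, peak, out_path = NULL, slice = 1L) {
  stopifnot(inherits(table, "data.frame"))
  if (!peak %in% table$component) {
    abort(sprintf("unknown peak component '%s'; available: %s.",
                  peak, paste(unique(table$component), collapse = ", ")),
          class = "mrsfit_error_validation")
  }
  sub <- dplyr::filter(table, .data$component == peak, .data$k == slice)
  sub <- dplyr::mutate(sub, amplitude = ifelse(.data$converged,
                                               .data$amplitude, NA_real_))
  ni <- max(sub$i); nj <- max(sub$j)
  map <- matrix(NA_real_, ni, nj)
  map[cbind(sub$i, sub$j)] <- sub$amplitude
  p <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$i, y = .data$j,
                                         fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "voxel i", y = "voxel j", fill = peak) +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, plot = p, width = 5, height = 4.2, dpi = 150)
  }
  invisible(list(plot = p, map = map))
}
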