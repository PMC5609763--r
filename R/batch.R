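#' Batch-fit a CSI grid, FID list, or file list
#'
#' Runs an independent AMARES fit per voxel (or per file) and collects one
#' row per (voxel, peak component) in deterministic row-major voxel order.
#' A voxel whose fit fails, does not converge, or is degenerate (zero
#' residual noise, e.g. an all-zero voxel, so no CRLBs exist) keeps its
#' rows with `converged = FALSE` and is never allowed to abort the run.
#' Voxel indices in the returned table are 1-based.
#'
#' @param source A [csi_grid()], a list of [fid_series()], or a character
#'   vector of file paths (`.json` fixtures via [read_fixture()], DICOM
#'   otherwise).
#' @param prior A [peak_prior()] tibble or a precompiled
#'   [compile_prior()] map.
#' @param options [amares_options()] for every fit.
#' @param derived Optional named list of derived expressions (see
#'   [derived_param_crlb()]); each adds `<name>` and `<name>_crlb` columns
#'   repeated over the voxel's rows. Entries may be strings or lists with
#'   fields `expression` and `constants`.
#' @return A `batch_result` tibble: voxel indices `i, j, k`, `voxel`
#'   (linear index), `component`, `peak`, estimates, CRLBs, derived
#'   columns, and `converged`.
#' @export
batch_fit <- function(source, prior, options = amares_options(),
                      derived = NULL) {
  if (inherits(source, "csi_grid")) {
    fids <- source$fids
    dims <- source$dims
  } else if (is.character(source)) {
    if (length(source) == 0) {
      abort("empty file list.", class = "mrsfit_error_validation")
    }
    fids <- lapply(source, function(p) {
      if (grepl("\\.json$", p, ignore.case = TRUE)) read_fixture(p)
      else read_spectroscopy(p)
    })
    if (any(vapply(fids, inherits, logical(1), what = "csi_grid"))) {
      abort("file list contains CSI grids; batch-fit each grid separately.",
            class = "mrsfit_error_validation")
    }
    dims <- c(length(fids), 1L, 1L)
  } else if (is.list(source) && length(source) > 0 &&
             all(vapply(source, inherits, logical(1), what = "fid_series"))) {
    fids <- source
    dims <- c(length(fids), 1L, 1L)
  } else {
    abort("`source` must be a csi_grid, a non-empty list of fid_series, or file paths.",
          class = "mrsfit_error_validation")
  }

  fid0 <- fids[[1]]
  cmap <- if (inherits(prior, "constraint_map")) prior else {
    compile_prior(prior, fid0$transmitter_freq, fid0$reference_shift)
  }

  idx_grid <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                          k = seq_len(dims[3]))
  rows <- purrr::map_dfr(seq_along(fids), function(v) {
    fit <- tryCatch(fit_amares(fids[[v]], cmap, options),
                    error = function(e) e)
    failed <- inherits(fit, "error")
    if (failed) {
      inform(sprintf("voxel %d: fit failed (%s)", v, conditionMessage(fit)))
      est <- tibble(component = cmap$components$component,
                    peak = cmap$components$parent,
                    amplitude = NA_real_, phase_deg = NA_real_,
                    linewidth_hz = NA_real_, shift_ppm = NA_real_,
                    amplitude_crlb = NA_real_, phase_crlb = NA_real_,
                    linewidth_crlb = NA_real_, shift_crlb = NA_real_)
      ok <- FALSE
    } else {
      est <- peak_estimates(fit)
      if (is.null(fit$crlbs)) {
        est$amplitude_crlb <- NA_real_
        est$phase_crlb <- NA_real_
        est$linewidth_crlb <- NA_real_
        est$shift_crlb <- NA_real_
      }
      ok <- fit$converged && fit$noise_sigma > 0
    }
    out <- dplyr::bind_cols(
      tibble(i = idx_grid$i[v], j = idx_grid$j[v], k = idx_grid$k[v],
             voxel = v),
      est)
    out$converged <- ok
    if (!is.null(derived) && !failed && !is.null(fit$covariance)) {
      for (nm in names(derived)) {
        spec <- derived[[nm]]
        if (is.character(spec)) spec <- list(expression = spec)
        dq <- tryCatch(
          derived_param_crlb(fit, spec$expression,
                             constants = spec$constants %||% c()),
          error = function(e) NULL)
        out[[nm]] <- if (is.null(dq)) NA_real_ else dq$value
        out[[paste0(nm, "_crlb")]] <- if (is.null(dq)) NA_real_ else dq$crlb
      }
    }
    out
  })
  class(rows) <- c("batch_result", class(rows))
  attr(rows, "dims") <- dims
  rows
}

#' Write or read a batch result table
#'
#' CSV at 12+ significant digits so tables round-trip without loss.
#'
#' @param table A [batch_fit()] result.
#' @param path CSV file path.
#' @return `write_batch_result()`: `path` invisibly; `read_batch_result()`:
#'   the table.
#' @export
write_batch_result <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1)) &
    !vapply(table, is.integer, logical(1))
  out <- table
  out[num] <- lapply(out[num], function(v) sprintf("%.15g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_batch_result
#' @export
read_batch_result <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  out$converged <- as.logical(out$converged)
  class(out) <- c("batch_result", class(out))
  out
}
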