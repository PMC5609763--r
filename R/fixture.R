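fixture_version <- 1L

# Full-precision (17 significant digit) JSON so doubles round-trip
# bit-exactly.
fixture_tojson <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17), null = "null")
}

fid_to_record <- function(fid) {
  rec <- list(
    dwell_time = fid$dwell_time,
    dead_time = fid$dead_time,
    transmitter_freq = fid$transmitter_freq,
    reference_shift = fid$reference_shift,
    nucleus = fid$nucleus,
    samples_re = Re(fid$samples),
    samples_im = Im(fid$samples))
  truth <- attr(fid, "truth")
  if (!is.null(truth)) {
    rec$truth <- as.list(truth[c("amplitude", "phase", "damping",
                                 "frequency", "lineshape_g")])
  }
  rec
}

require_field <- function(rec, field, path, where = "record") {
  if (is.null(rec[[field]])) {
    abort(sprintf("fixture file '%s': %s lacks required field '%s'.",
                  path, where, field),
          class = "mrsfit_error_schema")
  }
  rec[[field]]
}

record_to_fid <- function(rec, path, where = "fid record") {
  for (f in c("dwell_time", "transmitter_freq", "samples_re", "samples_im")) {
    require_field(rec, f, path, where)
  }
  fid <- fid_series(
    complex(real = rec$samples_re, imaginary = rec$samples_im),
    dwell_time = rec$dwell_time,
    dead_time = rec$dead_time %||% 0,
    transmitter_freq = rec$transmitter_freq,
    reference_shift = rec$reference_shift %||% 0,
    nucleus = rec$nucleus %||% "31P")
  if (!is.null(rec$truth)) {
    attr(fid, "truth") <- do.call(sinusoids, rec$truth)
  }
  fid
}

#' Write or read the plain-text fixture format
#'
#' A versioned JSON format storing a [fid_series()] or [csi_grid()] with
#' all metadata (and any attached ground truth) at full 17-digit decimal
#' precision, so `read_fixture(write_fixture(x))` reproduces `x`
#' bit-exactly without any DICOM machinery.
#'
#' @param x A [fid_series()] or [csi_grid()].
#' @param path File path (conventionally `.json`).
#' @return `write_fixture()`: `path`, invisibly. `read_fixture()`: the
#'   stored object.
#' @export
write_fixture <- function(x, path) {
  if (inherits(x, "fid_series")) {
    doc <- list(format = "mrsfit-fixture", version = fixture_version,
                type = "fid", fid = fid_to_record(x))
  } else if (inherits(x, "csi_grid")) {
    doc <- list(format = "mrsfit-fixture", version = fixture_version,
                type = "csi",
                csi = list(
                  dims = x$dims, position = x$position,
                  row_dir = x$row_dir, col_dir = x$col_dir,
                  slice_dir = x$slice_dir, voxel_size = x$voxel_size,
                  fids = lapply(x$fids, fid_to_record)))
    truth <- attr(x, "truth")
    if (!is.null(truth)) {
      doc$truth <- list(
        peaks = as.list(truth$peaks[c("amplitude", "phase", "damping",
                                      "frequency", "lineshape_g")]),
        amplitude_map = truth$amplitude_map,
        sigma = truth$sigma, seed = truth$seed)
    }
  } else {
    abort("`x` must be a fid_series or csi_grid.",
          class = "mrsfit_error_validation")
  }
  writeLines(fixture_tojson(doc), path)
  invisible(path)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(path) {
  stop_unless(file.exists(path), sprintf("fixture file '%s' not found.", path),
              class = "mrsfit_error_io")
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  if (!identical(doc$format, "mrsfit-fixture") ||
      !identical(as.integer(doc$version), fixture_version)) {
    abort(sprintf("fixture file '%s': unsupported or missing format/version (expected mrsfit-fixture v%d).",
                  path, fixture_version),
          class = "mrsfit_error_schema")
  }
  if (identical(doc$type, "fid")) {
    record_to_fid(require_field(doc, "fid", path, "document"), path)
  } else if (identical(doc$type, "csi")) {
    csi <- require_field(doc, "csi", path, "document")
    for (f in c("dims", "fids")) require_field(csi, f, path, "csi record")
    fids <- lapply(seq_along(csi$fids), function(i) {
      record_to_fid(csi$fids[[i]], path, sprintf("fid record %d", i))
    })
    grid <- csi_grid(fids, csi$dims,
                     position = csi$position %||% c(0, 0, 0),
                     row_dir = csi$row_dir %||% c(1, 0, 0),
                     col_dir = csi$col_dir %||% c(0, 1, 0),
                     slice_dir = csi$slice_dir %||% c(0, 0, 1),
                     voxel_size = csi$voxel_size %||% c(10, 10, 10))
    if (!is.null(doc$truth)) {
      peaks <- do.call(sinusoids, doc$truth$peaks)
      map <- doc$truth$amplitude_map
      if (!is.matrix(map)) map <- matrix(unlist(map), nrow = csi$dims[1])
      by_voxel <- lapply(seq_along(fids), function(v) attr(fids[[v]], "truth"))
      attr(grid, "truth") <- list(peaks = peaks, amplitude_map = map,
                                  by_voxel = by_voxel,
                                  sigma = doc$truth$sigma,
                                  seed = doc$truth$seed)
    }
    grid
  } else {
    abort(sprintf("fixture file '%s': unknown type '%s'.", path, doc$type),
          class = "mrsfit_error_schema")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
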