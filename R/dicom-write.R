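# Synthetic Siemens-style DICOM writer. Produces files laid out the way
# the importer expects real Siemens MR spectroscopy data: CSA private
# header under (0029,1110)/(0029,1120), complex FID samples as interleaved
# 32-bit float real/imaginary pairs under the private tag (7FE1,1010),
# geometry in the standard position/orientation/spacing tags. These files
# are synthetic fixtures for exercising the reader, not scanner output;
# two package-specific CSA tags (DeadTime_s, ReferenceShift_ppm) carry
# metadata real headers only encode indirectly.

mrsfit_uid_root <- "1.2.826.0.1.3680043.9.7435"

#' Generate a DICOM UID
#'
#' @param suffix Optional fixed suffix; by default a session-unique counter
#'   is appended to the package's UID root.
#' @return UID string.
#' @export
mrsfit_uid <- function(suffix = NULL) {
  if (is.null(suffix)) {
    n <- get0("uid_counter", .mrsfit_state, ifnotfound = 0L) + 1L
    assign("uid_counter", n, .mrsfit_state)
    suffix <- sprintf("%d.%d", as.integer(Sys.time()) %% 100000L, n)
  }
  paste0(mrsfit_uid_root, ".", suffix)
}

# Quantize doubles to 32-bit float precision (the on-disk sample format).
#' Round to 32-bit float precision
#'
#' DICOM spectroscopy sample data is stored as 32-bit floats; applying
#' this before writing makes write-then-read round trips bit-exact.
#'
#' @param x Numeric or complex vector.
#' @return `x` with each real channel rounded to float32 precision.
#' @export
float32_quantize <- function(x) {
  q <- function(v) readBin(writeBin(as.numeric(v), raw(), size = 4),
                           "numeric", n = length(v), size = 4)
  if (is.complex(x)) complex(real = q(Re(x)), imaginary = q(Im(x))) else q(x)
}

samples_to_float32 <- function(samples) {
  inter <- as.numeric(rbind(Re(samples), Im(samples)))
  writeBin(inter, raw(), size = 4, endian = "little")
}

spectro_common_elements <- function(fid, study, series, instance,
                                    csa_dialect, csa_tag, dims,
                                    position, row_dir, col_dir, voxel_size) {
  ds <- function(v) sprintf("%.10g", v)
  csa <- list(
    RealDwellTime = sprintf("%.17g", fid$dwell_time * 1e9),
    ImagingFrequency = sprintf("%.17g", fid$transmitter_freq),
    DataPointColumns = sprintf("%d", fid$n_points),
    ImagedNucleus = fid$nucleus,
    SpectroscopyAcquisitionPhaseColumns = sprintf("%d", dims[1]),
    SpectroscopyAcquisitionPhaseRows = sprintf("%d", dims[2]),
    `SpectroscopyAcquisitionOut-of-planePhaseSteps` = sprintf("%d", dims[3]),
    DeadTime_s = sprintf("%.17g", fid$dead_time),
    ReferenceShift_ppm = sprintf("%.17g", fid$reference_shift))
  list(
    "(0008,0020)" = dcm_element("DA", study$date %||% "20260101"),
    "(0008,0030)" = dcm_element("TM", "120000"),
    "(0008,0032)" = dcm_element("TM", instance$acq_time %||% "120000"),
    "(0008,0060)" = dcm_element("CS", "MR"),
    "(0008,1030)" = dcm_element("LO", study$description),
    "(0008,103e)" = dcm_element("LO", series$description),
    "(0020,000d)" = dcm_element("UI", study$uid),
    "(0020,000e)" = dcm_element("UI", series$uid),
    "(0020,0011)" = dcm_element("IS", sprintf("%d", series$number)),
    "(0020,0013)" = dcm_element("IS", sprintf("%d", instance$number)),
    "(0020,0032)" = dcm_element("DS", vapply(position, ds, character(1))),
    "(0020,0037)" = dcm_element("DS", vapply(c(row_dir, col_dir), ds, character(1))),
    "(0018,0050)" = dcm_element("DS", ds(voxel_size[3])),
    "(0018,0088)" = dcm_element("DS", ds(voxel_size[3])),
    "(0028,0030)" = dcm_element("DS", vapply(voxel_size[1:2], ds, character(1))),
    "(0029,0010)" = dcm_element("LO", "SIEMENS CSA HEADER"),
    "(7fe1,0010)" = dcm_element("LO", "SIEMENS CSA NON-IMAGE"),
    csa_placeholder = dcm_element(csa_tag, csa),
    csa_dialect = csa_dialect)
}

#' Write a synthetic Siemens-style spectroscopy DICOM file
#'
#' @param x A [fid_series()] (single voxel) or [csi_grid()].
#' @param path Output file path.
#' @param study,series List with fields `uid`, `description` (and
#'   `number`, `date` for series/study); sensible defaults are generated.
#' @param instance List with fields `number`, `acq_time`.
#' @param csa_dialect `"CSA2"` or `"CSA1"` private-header dialect.
#' @param explicit_vr Write explicit (default) or implicit VR little
#'   endian.
#' @return `path`, invisibly.
#' @export
write_spectroscopy_dicom <- function(x, path,
                                     study = list(), series = list(),
                                     instance = list(),
                                     csa_dialect = c("CSA2", "CSA1"),
                                     explicit_vr = TRUE) {
  csa_dialect <- match.arg(csa_dialect)
  study <- modifyList(list(uid = mrsfit_uid(), description = "synthetic study",
                           date = "20260101"), study)
  series <- modifyList(list(uid = mrsfit_uid(), description = "synthetic spectroscopy",
                            number = 1L), series)
  instance <- modifyList(list(number = 1L, acq_time = "120000"), instance)

  if (inherits(x, "fid_series")) {
    fid0 <- x
    dims <- c(1L, 1L, 1L)
    samples <- x$samples
    position <- c(0, 0, 0); row_dir <- c(1, 0, 0); col_dir <- c(0, 1, 0)
    voxel_size <- c(10, 10, 10)
  } else if (inherits(x, "csi_grid")) {
    fid0 <- x$fids[[1]]
    dims <- x$dims
    samples <- do.call(c, lapply(x$fids, function(f) f$samples))
    position <- x$position; row_dir <- x$row_dir; col_dir <- x$col_dir
    voxel_size <- x$voxel_size
  } else {
    abort("`x` must be a fid_series or csi_grid.",
          class = "mrsfit_error_validation")
  }

  csa_tag_key <- if (csa_dialect == "CSA2") "(0029,1110)" else "(0029,1120)"
  els <- spectro_common_elements(fid0, study, series, instance,
                                 csa_dialect, csa_tag_key, dims,
                                 position, row_dir, col_dir, voxel_size)
  csa <- els$csa_placeholder$value
  dialect <- els$csa_dialect
  els$csa_placeholder <- NULL
  els$csa_dialect <- NULL
  els[[csa_tag_key]] <- dcm_element("OB", csa_encode(csa, dialect))
  els[["(7fe1,1010)"]] <- dcm_element("OB", samples_to_float32(samples))
  dcm_write_file(path, els, sop_class = uid_siemens_csa_nonimage,
                 sop_instance = mrsfit_uid(), explicit = explicit_vr)
}

#' Write a synthetic DICOM localizer image
#'
#' A minimal MR Image Storage file (small uint16 pixel matrix plus
#' geometry), used to exercise tree scanning and the not-spectroscopy
#' error path of [read_spectroscopy()].
#'
#' @inheritParams write_spectroscopy_dicom
#' @param rows,cols Pixel matrix size.
#' @param pixel_data Integer matrix (`rows` x `cols`); defaults to a ramp.
#' @return `path`, invisibly.
#' @export
write_image_dicom <- function(path, study = list(), series = list(),
                              instance = list(), rows = 16L, cols = 16L,
                              pixel_data = NULL, explicit_vr = TRUE) {
  study <- modifyList(list(uid = mrsfit_uid(), description = "synthetic study",
                           date = "20260101"), study)
  series <- modifyList(list(uid = mrsfit_uid(), description = "synthetic localizer",
                            number = 99L), series)
  instance <- modifyList(list(number = 1L, acq_time = "115900"), instance)
  if (is.null(pixel_data)) {
    pixel_data <- matrix(seq_len(rows * cols) %% 4096L, rows, cols)
  }
  els <- list(
    "(0008,0020)" = dcm_element("DA", study$date),
    "(0008,0030)" = dcm_element("TM", "115900"),
    "(0008,0032)" = dcm_element("TM", instance$acq_time),
    "(0008,0060)" = dcm_element("CS", "MR"),
    "(0008,1030)" = dcm_element("LO", study$description),
    "(0008,103e)" = dcm_element("LO", series$description),
    "(0020,000d)" = dcm_element("UI", study$uid),
    "(0020,000e)" = dcm_element("UI", series$uid),
    "(0020,0011)" = dcm_element("IS", sprintf("%d", series$number)),
    "(0020,0013)" = dcm_element("IS", sprintf("%d", instance$number)),
    "(0020,0032)" = dcm_element("DS", c("0", "0", "0")),
    "(0020,0037)" = dcm_element("DS", c("1", "0", "0", "0", "1", "0")),
    "(0028,0010)" = dcm_element("US", as.integer(rows)),
    "(0028,0011)" = dcm_element("US", as.integer(cols)),
    "(0028,0030)" = dcm_element("DS", c("1", "1")),
    "(0028,0100)" = dcm_element("US", 16L),
    "(7fe0,0010)" = dcm_element("OW", writeBin(as.integer(pixel_data),
                                               raw(), size = 2,
                                               endian = "little")))
  dcm_write_file(path, els, sop_class = uid_mr_image,
                 sop_instance = mrsfit_uid(), explicit = explicit_vr)
}

#' Write a synthetic DICOMDIR index
#'
#' @param dir Directory in which to place the `DICOMDIR` file.
#' @param referenced_files Character vector of file paths relative to
#'   `dir`.
#' @return The DICOMDIR path, invisibly.
#' @export
write_dicomdir <- function(dir, referenced_files) {
  items <- lapply(referenced_files, function(f) {
    list("(0004,1430)" = dcm_element("CS", "IMAGE"),
         "(0004,1500)" = dcm_element("CS",
                                     strsplit(f, "/", fixed = TRUE)[[1]]))
  })
  els <- list("(0004,1220)" = dcm_element("SQ", items))
  path <- file.path(dir, "DICOMDIR")
  dcm_write_file(path, els, sop_class = uid_dicomdir,
                 sop_instance = mrsfit_uid(), explicit = TRUE)
  invisible(path)
}
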