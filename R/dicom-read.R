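#' Read a Siemens DICOM spectroscopy file
#'
#' Parses the DICOM dataset (explicit or implicit VR little endian,
#' auto-detected from the transfer syntax), decodes the Siemens CSA
#' private header — both the CSA1 and the `SV10` CSA2 binary dialects,
#' auto-detected from the header magic — and extracts the complex FID
#' samples (interleaved 32-bit float real/imaginary pairs from the private
#' data tag), acquisition metadata (dwell time, transmitter frequency,
#' number of points, CSI matrix size) and voxel geometry.
#'
#' @param path DICOM file path.
#' @return A [fid_series()] for single-voxel data, a [csi_grid()] for CSI.
#' @export
read_spectroscopy <- function(path) {
  dcm <- dcm_read_file(path)
  sop <- dcm_value(dcm, "(0008,0016)", default = "<missing>")
  if (!identical(sop, uid_siemens_csa_nonimage)) {
    abort(sprintf("'%s' is not a Siemens spectroscopy file: SOP class %s.",
                  path, sop),
          class = "mrsfit_error_not_spectroscopy")
  }
  csa_raw <- dcm_value(dcm, "(0029,1110)") %||% dcm_value(dcm, "(0029,1120)")
  if (is.null(csa_raw)) {
    abort(sprintf("'%s' carries no CSA header (0029,1110)/(0029,1120).", path),
          class = "mrsfit_error_dicom_parse")
  }
  csa <- csa_parse(as.raw(csa_raw))

  n_points <- csa_num(csa, "DataPointColumns")
  dwell_ns <- csa_num(csa, "RealDwellTime")
  f0 <- csa_num(csa, "ImagingFrequency")
  if (is.null(n_points) || is.null(dwell_ns) || is.null(f0)) {
    abort(sprintf("'%s': CSA header lacks DataPointColumns/RealDwellTime/ImagingFrequency.",
                  path),
          class = "mrsfit_error_dicom_parse")
  }
  dims <- c(csa_num(csa, "SpectroscopyAcquisitionPhaseColumns", 1),
            csa_num(csa, "SpectroscopyAcquisitionPhaseRows", 1),
            csa_num(csa, "SpectroscopyAcquisitionOut-of-planePhaseSteps", 1))
  dead_time <- csa_num(csa, "DeadTime_s", 0)
  ref_shift <- csa_num(csa, "ReferenceShift_ppm", 0)
  nucleus <- (csa[["ImagedNucleus"]] %||% "31P")[1]

  data_raw <- dcm_value(dcm, "(7fe1,1010)")
  if (is.null(data_raw)) {
    abort(sprintf("'%s' carries no spectroscopy data tag (7FE1,1010).", path),
          class = "mrsfit_error_dicom_parse")
  }
  n_expect <- 2 * n_points * prod(dims)
  vals <- readBin(as.raw(data_raw), "numeric", n = n_expect, size = 4,
                  endian = "little")
  if (length(vals) < n_expect) {
    abort(sprintf("'%s': expected %d float32 values in (7FE1,1010), found %d.",
                  path, n_expect, length(vals)),
          class = "mrsfit_error_dicom_parse")
  }
  make_fid <- function(v) {
    fid_series(complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)]),
               dwell_time = dwell_ns * 1e-9, dead_time = dead_time,
               transmitter_freq = f0, reference_shift = ref_shift,
               nucleus = nucleus)
  }
  if (all(dims == 1)) {
    return(make_fid(vals))
  }
  position <- as.numeric(dcm_value(dcm, "(0020,0032)", default = c(0, 0, 0)))
  orient <- as.numeric(dcm_value(dcm, "(0020,0037)",
                                 default = c(1, 0, 0, 0, 1, 0)))
  row_dir <- orient[1:3]; col_dir <- orient[4:6]
  slice_dir <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
                 row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
                 row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  spacing <- as.numeric(dcm_value(dcm, "(0028,0030)", default = c(10, 10)))
  thickness <- as.numeric(dcm_value(dcm, "(0018,0050)", default = 10))
  per_vox <- 2 * n_points
  fids <- lapply(seq_len(prod(dims)), function(v) {
    make_fid(vals[seq.int((v - 1) * per_vox + 1, length.out = per_vox)])
  })
  csi_grid(fids, dims, position = position, row_dir = row_dir,
           col_dir = col_dir, slice_dir = slice_dir,
           voxel_size = c(spacing, thickness))
}

# Instance-level summary used by the tree scanner; NULL if not DICOM.
dicom_instance_record <- function(path) {
  dcm <- tryCatch(dcm_read_file(path), error = function(e) e)
  if (inherits(dcm, "error")) {
    looks_dicom <- inherits(dcm, "mrsfit_error_dicom_parse")
    if (looks_dicom) {
      warn(sprintf("skipping unreadable DICOM file '%s': %s",
                   path, conditionMessage(dcm)),
           class = "mrsfit_warning_skipped_file")
    }
    return(NULL)
  }
  first_or <- function(key, default) {
    v <- dcm_value(dcm, key)
    if (is.null(v) || length(v) == 0) default else v[1]
  }
  tibble(
    study_uid = first_or("(0020,000d)", NA_character_),
    study_description = first_or("(0008,1030)", NA_character_),
    series_uid = first_or("(0020,000e)", NA_character_),
    series_description = first_or("(0008,103e)", NA_character_),
    series_number = suppressWarnings(as.integer(first_or("(0020,0011)", NA))),
    instance_uid = first_or("(0008,0018)", NA_character_),
    instance_number = suppressWarnings(as.integer(first_or("(0020,0013)", NA))),
    sop_class = first_or("(0008,0016)", NA_character_),
    acquisition_time = first_or("(0008,0032)", NA_character_),
    path = path)
}

# Referenced file paths from a DICOMDIR dataset (relative to its folder).
dicomdir_referenced_files <- function(path) {
  dcm <- tryCatch(dcm_read_file(path), error = function(e) NULL)
  if (is.null(dcm) ||
      !identical(dcm_value(dcm, "(0008,0016)"), uid_dicomdir)) {
    return(character(0))
  }
  seq_el <- dcm$elements[["(0004,1220)"]]
  if (is.null(seq_el)) return(character(0))
  refs <- vapply(seq_el$value, function(item) {
    comp <- item[["(0004,1500)"]]$value
    if (is.null(comp)) NA_character_ else paste(comp, collapse = "/")
  }, character(1))
  refs[!is.na(refs)]
}
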