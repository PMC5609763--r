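# DICOM I/O: fixture format, synthetic Siemens-style files (CSA1/CSA2,
# explicit/implicit VR), directory scanning with cache, DICOMDIR, and
# voxel geometry.

quantized_fid <- function(n = 64, seed = 1) {
  meta <- test_meta(n = n, dead = 1e-4, ref = 0.4)
  fid <- simulate_fid(two_peak_truth(), meta, sigma = 0.1, seed = seed)
  fid$samples <- float32_quantize(fid$samples)
  fid
}

test_that("fixture round-trip is bit-exact for FIDs and CSI grids", {
  fid <- simulate_fid(two_peak_truth(), test_meta(n = 1024, dead = 2e-4),
                      sigma = 0.2, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_fixture(fid, path)
  back <- read_fixture(path)
  expect_identical(back$samples, fid$samples)
  expect_identical(back[c("dwell_time", "dead_time", "transmitter_freq",
                          "reference_shift", "nucleus")],
                   fid[c("dwell_time", "dead_time", "transmitter_freq",
                         "reference_shift", "nucleus")])
  expect_equal(attr(back, "truth")$amplitude, attr(fid, "truth")$amplitude)

  grid <- simulate_csi_phantom(dims = c(8, 8, 1), sigma = 0.03, seed = 3,
                               position = c(-40.5, 12.25, 3),
                               voxel_size = c(12.5, 12.5, 8))
  gpath <- withr::local_tempfile(fileext = ".json")
  write_fixture(grid, gpath)
  gback <- read_fixture(gpath)
  expect_identical(lapply(gback$fids, `[[`, "samples"),
                   lapply(grid$fids, `[[`, "samples"))
  expect_identical(gback$position, grid$position)
  expect_identical(gback$voxel_size, grid$voxel_size)
  expect_equal(attr(gback, "truth")$amplitude_map,
               attr(grid, "truth")$amplitude_map)
})

test_that("fixture schema violations raise errors naming the field", {
  fid <- quantized_fid()
  path <- withr::local_tempfile(fileext = ".json")
  write_fixture(fid, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  doc$fid$dwell_time <- NULL
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), bad)
  expect_error(read_fixture(bad), regexp = "dwell_time",
               class = "mrsfit_error_schema")
  doc2 <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  doc2$version <- 999
  writeLines(jsonlite::toJSON(doc2, auto_unbox = TRUE, digits = NA), bad)
  expect_error(read_fixture(bad), class = "mrsfit_error_schema")
})

test_that("synthetic spectroscopy DICOM inverts samples bit-exactly in both dialects", {
  fid <- quantized_fid(n = 96)
  for (spec in list(list(d = "CSA2", e = TRUE), list(d = "CSA1", e = TRUE),
                    list(d = "CSA2", e = FALSE))) {
    path <- withr::local_tempfile(fileext = ".dcm")
    write_spectroscopy_dicom(fid, path, csa_dialect = spec$d,
                             explicit_vr = spec$e)
    back <- read_spectroscopy(path)
    expect_identical(back$samples, fid$samples)
    expect_equal(back$dwell_time, fid$dwell_time, tolerance = 1e-15)
    expect_equal(back$dead_time, fid$dead_time)
    expect_equal(back$transmitter_freq, fid$transmitter_freq)
    expect_equal(back$reference_shift, fid$reference_shift)
    expect_identical(back$nucleus, fid$nucleus)
  }
})

test_that("a CSI DICOM yields a grid with the constructed dims and geometry", {
  grid <- simulate_csi_phantom(dims = c(8, 8, 1), sigma = 0.02, seed = 6,
                               fid = test_meta(n = 32),
                               position = c(-35, -35, 10),
                               voxel_size = c(10, 10, 8))
  for (i in seq_along(grid$fids)) {
    grid$fids[[i]]$samples <- float32_quantize(grid$fids[[i]]$samples)
  }
  path <- withr::local_tempfile(fileext = ".dcm")
  write_spectroscopy_dicom(grid, path)
  back <- read_spectroscopy(path)
  expect_s3_class(back, "csi_grid")
  expect_equal(back$dims, c(8L, 8L, 1L))
  expect_length(back$fids, 64)
  expect_identical(lapply(back$fids, `[[`, "samples"),
                   lapply(grid$fids, `[[`, "samples"))
  expect_equal(back$position, grid$position)
  expect_equal(back$voxel_size, grid$voxel_size)
})

test_that("non-spectroscopy DICOM raises a typed error naming the SOP class", {
  path <- withr::local_tempfile(fileext = ".dcm")
  write_image_dicom(path)
  err <- expect_error(read_spectroscopy(path),
                      class = "mrsfit_error_not_spectroscopy")
  expect_match(conditionMessage(err), "1.2.840.10008.5.1.4.1.1.4",
               fixed = TRUE)
})

test_that("a truncated CSA block raises a parse error with a byte offset", {
  fid <- quantized_fid(n = 16)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_spectroscopy_dicom(fid, path)
  dcm <- mrsfit:::dcm_read_file(path)
  csa <- as.raw(dcm$elements[["(0029,1110)"]]$value)
  err <- expect_error(mrsfit:::csa_parse(csa[1:40]),
                      class = "mrsfit_error_dicom_parse")
  expect_match(conditionMessage(err), "offset")
})

test_that("pydicom independently reads the synthetic spectroscopy file", {
  python <- Sys.which("python")
  skip_if(python == "", "python not on PATH")
  fid <- quantized_fid(n = 32)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_spectroscopy_dicom(fid, path)
  ref <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%.17g", as.numeric(rbind(Re(fid$samples),
                                               Im(fid$samples)))), ref)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, struct, pydicom",
    "d = pydicom.dcmread(sys.argv[1])",
    "raw = d[0x7fe1, 0x1010].value",
    "vals = struct.unpack('<%df' % (len(raw) // 4), raw)",
    "truth = [float(x) for x in open(sys.argv[2])]",
    "assert d.SOPClassUID == '1.3.12.2.1107.5.9.1'",
    "assert len(vals) == len(truth)",
    "assert all(a == b for a, b in zip(vals, truth))",
    "print('OK')"), script)
  out <- tryCatch(system2(python, c(script, path, ref), stdout = TRUE,
                          stderr = TRUE),
                  warning = function(w) w)
  skip_if(inherits(out, "warning") &&
            any(grepl("ModuleNotFoundError", unlist(out))),
          "pydicom not importable")
  expect_equal(tail(unlist(out), 1), "OK")
})

test_that("directory scan matches a constructed 2x3x4 study/series/instance tree", {
  root <- withr::local_tempdir()
  fid <- quantized_fid(n = 16)
  for (st in 1:2) {
    study <- list(uid = mrsfit_uid(sprintf("st%d", st)),
                  description = sprintf("study %d", st))
    for (se in 1:3) {
      series <- list(uid = mrsfit_uid(sprintf("st%d.se%d", st, se)),
                     description = sprintf("series %d", se), number = se)
      for (in_ in 1:4) {
        sub <- file.path(root, sprintf("s%d/e%d", st, se))
        dir.create(sub, recursive = TRUE, showWarnings = FALSE)
        write_spectroscopy_dicom(
          fid, file.path(sub, sprintf("i%d.dcm", in_)),
          study = study, series = series, instance = list(number = in_))
      }
    }
  }
  writeLines("not dicom at all", file.path(root, "readme.txt"))
  tree <- scan_dicom_tree(root)
  expect_equal(nrow(tree), 24L)
  expect_equal(dplyr::n_distinct(tree$study_uid), 2L)
  expect_equal(dplyr::n_distinct(tree$series_uid), 6L)
  counts <- dplyr::count(as_tibble(tree), .data$study_uid, .data$series_uid)
  expect_true(all(counts$n == 4L))
  # instances ordered by instance number within series
  by_series <- split(tree$instance_number, tree$series_uid)
  expect_true(all(vapply(by_series, function(v) all(v == 1:4), logical(1))))

  # search helpers
  hit <- find_series(tree, description = "series 2")
  expect_equal(nrow(hit), 8L)
  expect_equal(nrow(find_series(tree, number = 3)), 8L)
  expect_equal(nrow(find_series(tree, uid = tree$series_uid[1])), 4L)
})

test_that("warm rescan from cache reproduces the tree identically", {
  root <- withr::local_tempdir()
  fid <- quantized_fid(n = 16)
  for (i in 1:3) {
    write_spectroscopy_dicom(fid, file.path(root, sprintf("f%d.dcm", i)),
                             instance = list(number = i))
  }
  t1 <- scan_dicom_tree(root)
  t2 <- scan_dicom_tree(root)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # a new file is picked up on rescan despite the warm cache
  write_spectroscopy_dicom(fid, file.path(root, "f4.dcm"),
                           instance = list(number = 4))
  t3 <- scan_dicom_tree(root)
  expect_equal(nrow(t3), nrow(t1) + 1L)
  # corrupt cache is discarded and rebuilt
  cache <- mrsfit:::dicom_tree_cache_file(root)
  writeLines("garbage", cache)
  t4 <- scan_dicom_tree(root)
  expect_identical(as.data.frame(t4), as.data.frame(t3))
})

test_that("empty directories scan to empty trees and DICOMDIR refs resolve", {
  empty <- withr::local_tempdir()
  tree <- scan_dicom_tree(empty)
  expect_equal(nrow(tree), 0L)

  root <- withr::local_tempdir()
  fid <- quantized_fid(n = 16)
  dir.create(file.path(root, "DATA"))
  write_spectroscopy_dicom(fid, file.path(root, "DATA", "A.dcm"))
  write_dicomdir(root, "DATA/A.dcm")
  tree2 <- scan_dicom_tree(root)
  # DICOMDIR itself is an index, not an instance
  expect_equal(nrow(tree2), 1L)
  expect_match(tree2$path, "A.dcm")
})

test_that("voxel-to-patient mapping matches a homogeneous-matrix oracle", {
  # random but orthonormal orientation from a QR decomposition
  set.seed(42)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  vox <- c(7.5, 11, 4.2)
  pos <- c(-31.7, 12.9, 88.1)
  fids <- replicate(2 * 3 * 4, quantized_fid(n = 8), simplify = FALSE)
  grid <- csi_grid(fids, dims = c(2, 3, 4), position = pos,
                   row_dir = Q[, 1], col_dir = Q[, 2], slice_dir = Q[, 3],
                   voxel_size = vox)
  oracle <- rbind(cbind(Q %*% diag(vox), pos), c(0, 0, 0, 1))
  for (idx in list(c(0, 0, 0), c(1, 2, 3), c(1, 0, 2))) {
    expect_lt(max(abs(voxel_to_patient(grid, idx) -
                        (oracle %*% c(idx, 1))[1:3])), 1e-9)
  }
  expect_error(voxel_to_patient(grid, c(2, 0, 0)),
               class = "mrsfit_error_validation")

  # all voxel centres form a regular lattice: constant spacing along i
  centres <- vapply(0:(grid$dims[1] - 1),
                    function(i) voxel_to_patient(grid, c(i, 0, 0)),
                    numeric(3))
  steps <- diff(t(centres))
  expect_lt(max(abs(sweep(steps, 2, steps[1, ]))), 1e-9)
})
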