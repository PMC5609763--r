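dicom_tree_cache_version <- 1L

dicom_tree_cache_file <- function(directory) {
  key <- rlang::hash(normalizePath(directory, mustWork = FALSE))
  file.path(tempdir(), sprintf("mrsfit-dicomtree-%s-v%d.rds",
                               key, dicom_tree_cache_version))
}

#' Scan a directory tree for DICOM files
#'
#' Recursively scans a folder (including any `DICOMDIR` indexes, whose
#' referenced files are resolved relative to the index) and sorts every
#' readable DICOM file into a study / series / instance hierarchy.
#' Instance metadata is cached in the session temporary directory keyed by
#' the folder path; a warm rescan re-reads only files whose size or
#' modification time changed, so large archives rescan quickly. A corrupt
#' or version-mismatched cache is discarded and rebuilt silently.
#' Unreadable or non-DICOM files are skipped (with a warning for files
#' that look like DICOM but fail to parse).
#'
#' @param directory Folder to scan.
#' @param use_cache Consult and update the scan cache (default `TRUE`).
#' @return A `dicom_tree`: a tibble with one row per instance (study,
#'   series and instance UIDs, descriptions, numbers, acquisition time,
#'   path), ordered by study, series and instance number, with class
#'   `dicom_tree`.
#' @seealso [find_series()], [read_spectroscopy()]
#' @export
scan_dicom_tree <- function(directory, use_cache = TRUE) {
  stop_unless(dir.exists(directory),
              sprintf("directory '%s' does not exist.", directory),
              class = "mrsfit_error_io")
  files <- list.files(directory, recursive = TRUE, full.names = TRUE,
                      all.files = FALSE)
  # resolve DICOMDIR references (usually already covered by the recursive
  # listing; kept for indexes pointing at sibling folders)
  dicomdirs <- files[toupper(basename(files)) == "DICOMDIR"]
  for (dd in dicomdirs) {
    refs <- file.path(dirname(dd), dicomdir_referenced_files(dd))
    files <- c(files, refs[file.exists(refs)])
  }
  files <- setdiff(unique(normalizePath(files, mustWork = FALSE)),
                   normalizePath(dicomdirs, mustWork = FALSE))
  info <- file.info(files)
  stamp <- tibble(path = files,
                  mtime = as.numeric(info$mtime),
                  size = as.numeric(info$size))

  cache_path <- dicom_tree_cache_file(directory)
  cache <- NULL
  if (use_cache && file.exists(cache_path)) {
    cache <- tryCatch(readRDS(cache_path), error = function(e) NULL)
    if (!is.list(cache) ||
        !identical(cache$version, dicom_tree_cache_version)) {
      cache <- NULL
    }
  }

  records <- vector("list", length(files))
  cached_idx <- if (is.null(cache)) rep(FALSE, length(files)) else {
    m <- match(stamp$path, cache$stamp$path)
    !is.na(m) & stamp$mtime == cache$stamp$mtime[m] &
      stamp$size == cache$stamp$size[m]
  }
  for (i in seq_along(files)) {
    if (cached_idx[i]) {
      m <- match(stamp$path[i], cache$stamp$path)
      records[[i]] <- cache$records[[m]]
    } else {
      records[[i]] <- dicom_instance_record(files[i])
    }
  }
  if (use_cache) {
    saveRDS(list(version = dicom_tree_cache_version, stamp = stamp,
                 records = records), cache_path)
  }

  tree <- dplyr::bind_rows(purrr::compact(records))
  if (nrow(tree) == 0) {
    tree <- dicom_instance_record_prototype()
  }
  tree <- dplyr::arrange(tree, .data$study_uid, .data$series_number,
                         .data$series_uid, .data$instance_number)
  class(tree) <- c("dicom_tree", class(tree))
  attr(tree, "directory") <- directory
  tree
}

dicom_instance_record_prototype <- function() {
  tibble(study_uid = character(0), study_description = character(0),
         series_uid = character(0), series_description = character(0),
         series_number = integer(0), instance_uid = character(0),
         instance_number = integer(0), sop_class = character(0),
         acquisition_time = character(0), path = character(0))
}

#' @export
print.dicom_tree <- function(x, ...) {
  cat(sprintf("<dicom_tree> %d instance(s), %d series, %d study(ies) under %s\n",
              nrow(x), dplyr::n_distinct(x$series_uid),
              dplyr::n_distinct(x$study_uid),
              attr(x, "directory") %||% "?"))
  NextMethod()
}

#' Find series in a scanned DICOM tree
#'
#' @param tree A [scan_dicom_tree()] result.
#' @param uid Exact series UID to match.
#' @param description Regular expression matched against the series
#'   description.
#' @param number Series number to match.
#' @return The matching instance rows.
#' @export
find_series <- function(tree, uid = NULL, description = NULL, number = NULL) {
  out <- tree
  if (!is.null(uid)) out <- dplyr::filter(out, .data$series_uid == uid)
  if (!is.null(description)) {
    out <- dplyr::filter(out, grepl(description, .data$series_description))
  }
  if (!is.null(number)) out <- dplyr::filter(out, .data$series_number == number)
  out
}
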