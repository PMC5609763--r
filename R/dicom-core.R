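# Low-level DICOM binary encoding/decoding (little-endian, explicit and
# implicit VR), sufficient for Siemens MR spectroscopy files, localizer
# images and DICOMDIR indexes. Elements are held as a named list keyed by
# "(gggg,eeee)" (lower-case hex) with fields vr and value; SQ values are
# lists of item element-lists.

uid_explicit_le <- "1.2.840.10008.1.2.1"
uid_implicit_le <- "1.2.840.10008.1.2"
uid_dicomdir <- "1.2.840.10008.1.3.10"
uid_mr_image <- "1.2.840.10008.5.1.4.1.1.4"
uid_siemens_csa_nonimage <- "1.3.12.2.1107.5.9.1"

# VRs using the 2-byte-reserved + 4-byte-length explicit layout
dcm_long_vrs <- c("OB", "OW", "OF", "OD", "SQ", "UT", "UN", "UC", "UR")
# VRs whose values are backslash-joined ASCII strings
dcm_string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                    "PN", "SH", "ST", "TM", "UI", "UT", "UC", "UR")

# uint16 writer safe for values above 32767 (writeBin size=2 is signed)
w_uint16 <- function(v) {
  v <- as.integer(v)
  v <- ifelse(v > 32767L, v - 65536L, v)
  writeBin(v, raw(), size = 2, endian = "little")
}

dcm_tag_key <- function(group, element) {
  sprintf("(%04x,%04x)", group, element)
}

dcm_parse_key <- function(key) {
  c(strtoi(substr(key, 2, 5), 16L), strtoi(substr(key, 7, 10), 16L))
}

# --- value encoding ---------------------------------------------------

dcm_encode_value <- function(vr, value) {
  if (vr %in% dcm_string_vrs) {
    s <- paste(as.character(value), collapse = "\\")
    raw_s <- charToRaw(s)
    if (length(raw_s) %% 2 == 1) {
      pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
      raw_s <- c(raw_s, pad)
    }
    raw_s
  } else if (vr == "UL") {
    writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr == "US") {
    writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr == "SL") {
    writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr == "SS") {
    writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr == "FL" || vr == "OF") {
    writeBin(as.numeric(value), raw(), size = 4, endian = "little")
  } else if (vr == "FD" || vr == "OD") {
    writeBin(as.numeric(value), raw(), size = 8, endian = "little")
  } else if (vr %in% c("OB", "OW", "UN")) {
    as.raw(value)
  } else {
    abort(sprintf("cannot encode VR '%s'.", vr), class = "mrsfit_error_dicom")
  }
}

dcm_decode_value <- function(vr, bytes) {
  if (vr %in% dcm_string_vrs) {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    s <- sub("[ ]+$", "", s)
    strsplit(s, "\\", fixed = TRUE)[[1]]
  } else if (vr == "UL") {
    readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
            endian = "little")
  } else if (vr == "US") {
    readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
            signed = FALSE, endian = "little")
  } else if (vr == "SL") {
    readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
            endian = "little")
  } else if (vr == "SS") {
    readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
            endian = "little")
  } else if (vr == "FL" || vr == "OF") {
    readBin(bytes, "numeric", n = length(bytes) / 4, size = 4,
            endian = "little")
  } else if (vr == "FD" || vr == "OD") {
    readBin(bytes, "numeric", n = length(bytes) / 8, size = 8,
            endian = "little")
  } else {
    bytes  # OB/OW/UN and anything unknown stay raw
  }
}

# --- element encoding -------------------------------------------------

dcm_encode_element <- function(group, element, vr, value, explicit = TRUE) {
  if (vr == "SQ") {
    body <- do.call(c, lapply(value, function(item) {
      item_body <- dcm_encode_dataset(item, explicit = explicit)
      c(w_uint16(c(0xFFFE, 0xE000)),
        writeBin(length(item_body), raw(), size = 4, endian = "little"),
        item_body)
    }))
    if (is.null(body)) body <- raw(0)
  } else {
    body <- dcm_encode_value(vr, value)
  }
  head <- w_uint16(c(group, element))
  if (explicit) {
    if (vr %in% dcm_long_vrs) {
      c(head, charToRaw(vr), as.raw(c(0, 0)),
        writeBin(length(body), raw(), size = 4, endian = "little"), body)
    } else {
      c(head, charToRaw(vr),
        writeBin(length(body), raw(), size = 2, endian = "little"), body)
    }
  } else {
    c(head, writeBin(length(body), raw(), size = 4, endian = "little"), body)
  }
}

# elements: named list key -> list(vr, value), keys sorted on write
dcm_encode_dataset <- function(elements, explicit = TRUE) {
  keys <- names(elements)
  keys <- keys[order(keys)]
  do.call(c, c(list(raw(0)), lapply(keys, function(k) {
    tg <- dcm_parse_key(k)
    el <- elements[[k]]
    dcm_encode_element(tg[1], tg[2], el$vr, el$value, explicit = explicit)
  })))
}

# --- parsing ----------------------------------------------------------

# Implicit-VR files carry no VR; this dictionary covers the tags the
# package writes/reads. Unknown tags decode as UN (raw).
dcm_vr_dictionary <- c(
  "(0002,0002)" = "UI", "(0002,0003)" = "UI", "(0002,0010)" = "UI",
  "(0004,1220)" = "SQ", "(0004,1430)" = "CS", "(0004,1500)" = "CS",
  "(0008,0016)" = "UI", "(0008,0018)" = "UI", "(0008,0020)" = "DA",
  "(0008,0021)" = "DA", "(0008,0030)" = "TM", "(0008,0031)" = "TM",
  "(0008,0032)" = "TM", "(0008,0060)" = "CS", "(0008,1030)" = "LO",
  "(0008,103e)" = "LO",
  "(0018,0050)" = "DS", "(0018,0088)" = "DS",
  "(0020,000d)" = "UI", "(0020,000e)" = "UI", "(0020,0011)" = "IS",
  "(0020,0013)" = "IS", "(0020,0032)" = "DS", "(0020,0037)" = "DS",
  "(0028,0010)" = "US", "(0028,0011)" = "US", "(0028,0030)" = "DS",
  "(0028,0100)" = "US",
  "(0029,0010)" = "LO", "(0029,1110)" = "OB", "(0029,1120)" = "OB",
  "(7fe0,0010)" = "OW", "(7fe1,0010)" = "LO", "(7fe1,1010)" = "OB")

dcm_lookup_vr <- function(key) {
  vr <- dcm_vr_dictionary[[key]]
  if (is.null(vr)) "UN" else vr
}

# Stateful cursor over a raw vector.
dcm_cursor <- function(bytes, pos = 1L) {
  env <- new.env(parent = emptyenv())
  env$bytes <- bytes
  env$pos <- pos
  env
}

cur_take <- function(cur, n, what = "data") {
  if (cur$pos + n - 1L > length(cur$bytes)) {
    abort(sprintf("truncated DICOM stream: needed %d byte(s) for %s at offset %d.",
                  n, what, cur$pos - 1L),
          class = "mrsfit_error_dicom_parse")
  }
  out <- cur$bytes[seq.int(cur$pos, length.out = n)]
  cur$pos <- cur$pos + as.integer(n)
  out
}

cur_uint16 <- function(cur, what = "uint16") {
  readBin(cur_take(cur, 2L, what), "integer", size = 2, signed = FALSE,
          endian = "little")
}

cur_uint32 <- function(cur, what = "uint32") {
  v <- readBin(cur_take(cur, 4L, what), "integer", size = 4,
               endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

# Parse one dataset until the cursor is exhausted or `limit` is reached.
dcm_parse_dataset <- function(cur, explicit, limit = length(cur$bytes)) {
  elements <- list()
  while (cur$pos <= limit) {
    group <- cur_uint16(cur, "tag group")
    element <- cur_uint16(cur, "tag element")
    if (group == 0xFFFE) {  # item delimiters inside undefined-length SQ
      cur_uint32(cur, "delimiter length")
      if (element == 0xE00D || element == 0xE0DD) break
      next
    }
    key <- dcm_tag_key(group, element)
    if (explicit) {
      vr <- rawToChar(cur_take(cur, 2L, "VR"))
      if (vr %in% dcm_long_vrs) {
        cur_take(cur, 2L, "reserved")
        len <- cur_uint32(cur, "length")
      } else {
        len <- cur_uint16(cur, "length")
      }
    } else {
      vr <- dcm_lookup_vr(key)
      len <- cur_uint32(cur, "length")
    }
    if (vr == "SQ") {
      elements[[key]] <- list(vr = vr, value = dcm_parse_sq(cur, explicit, len))
    } else if (len == 4294967295) {
      abort(sprintf("undefined-length element %s with VR %s is not supported at offset %d.",
                    key, vr, cur$pos - 1L),
            class = "mrsfit_error_dicom_parse")
    } else {
      bytes <- cur_take(cur, len, sprintf("value of %s", key))
      elements[[key]] <- list(vr = vr, value = dcm_decode_value(vr, bytes))
    }
  }
  elements
}

dcm_parse_sq <- function(cur, explicit, len) {
  items <- list()
  end_pos <- if (len == 4294967295) Inf else cur$pos + len
  while (cur$pos < min(end_pos, length(cur$bytes) + 1L)) {
    group <- cur_uint16(cur, "item tag group")
    element <- cur_uint16(cur, "item tag element")
    ilen <- cur_uint32(cur, "item length")
    if (group == 0xFFFE && element == 0xE0DD) break  # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000)) {
      abort(sprintf("malformed sequence item tag at offset %d.", cur$pos - 9L),
            class = "mrsfit_error_dicom_parse")
    }
    if (ilen == 4294967295) {
      items[[length(items) + 1L]] <- dcm_parse_dataset(cur, explicit)
    } else {
      sub <- dcm_cursor(cur_take(cur, ilen, "sequence item"))
      items[[length(items) + 1L]] <- dcm_parse_dataset(sub, explicit)
    }
  }
  items
}

# --- file-level read/write -------------------------------------------

dcm_element <- function(vr, value) list(vr = vr, value = value)

#' @noRd
dcm_write_file <- function(path, elements, sop_class, sop_instance,
                           explicit = TRUE) {
  ts <- if (explicit) uid_explicit_le else uid_implicit_le
  meta <- list(
    "(0002,0002)" = dcm_element("UI", sop_class),
    "(0002,0003)" = dcm_element("UI", sop_instance),
    "(0002,0010)" = dcm_element("UI", ts))
  meta_body <- dcm_encode_dataset(meta, explicit = TRUE)
  meta_len <- dcm_encode_element(0x0002, 0x0000, "UL", length(meta_body),
                                 explicit = TRUE)
  elements[["(0008,0016)"]] <- dcm_element("UI", sop_class)
  elements[["(0008,0018)"]] <- dcm_element("UI", sop_instance)
  body <- dcm_encode_dataset(elements, explicit = explicit)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta_len, meta_body, body), con)
  invisible(path)
}

# Reads a DICOM file into list(meta, elements, transfer_syntax). Files
# without the DICM preamble are rejected.
dcm_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 132 ||
      !identical(rawToChar(bytes[129:132]), "DICM")) {
    abort(sprintf("'%s' is not a DICOM file (missing DICM preamble).", path),
          class = "mrsfit_error_dicom")
  }
  cur <- dcm_cursor(bytes, pos = 133L)
  # file meta group is always explicit LE; read its declared length first
  group <- cur_uint16(cur); element <- cur_uint16(cur)
  if (group != 0x0002 || element != 0x0000) {
    abort(sprintf("'%s': file meta group length element missing.", path),
          class = "mrsfit_error_dicom_parse")
  }
  cur_take(cur, 2L)  # "UL"
  cur_uint16(cur)
  meta_len <- cur_uint32(cur, "meta group length")
  meta_cur <- dcm_cursor(cur_take(cur, meta_len, "file meta group"))
  meta <- dcm_parse_dataset(meta_cur, explicit = TRUE)
  ts <- meta[["(0002,0010)"]]$value %||% uid_explicit_le
  explicit <- !identical(ts, uid_implicit_le)
  elements <- dcm_parse_dataset(cur, explicit = explicit)
  list(path = path, meta = meta, elements = elements, transfer_syntax = ts)
}

dcm_value <- function(dcm, key, default = NULL) {
  el <- dcm$elements[[key]]
  if (is.null(el)) default else el$value
}
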