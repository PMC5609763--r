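# Siemens CSA private header block: two binary dialects. CSA2 starts with
# the magic "SV10"; CSA1 has no magic and starts directly with the tag
# count. Both hold a list of named tags, each with a VR string, a value
# multiplicity, and a list of ASCII items padded to 4-byte boundaries.
# The reader auto-detects the dialect from the magic.

csa_pad4 <- function(bytes) {
  pad <- (4 - length(bytes) %% 4) %% 4
  c(bytes, raw(pad))
}

csa_name64 <- function(name) {
  raw_name <- charToRaw(name)
  if (length(raw_name) > 63) {
    abort(sprintf("CSA tag name '%s' exceeds 63 bytes.", name),
          class = "mrsfit_error_dicom")
  }
  c(raw_name, raw(64 - length(raw_name)))
}

w_uint32 <- function(v) {
  v <- as.numeric(v)
  v <- ifelse(v > 2147483647, v - 4294967296, v)
  writeBin(as.integer(v), raw(), size = 4, endian = "little")
}

#' @noRd
csa_encode <- function(tags, dialect = c("CSA2", "CSA1")) {
  dialect <- match.arg(dialect)
  body <- do.call(c, c(list(raw(0)), lapply(names(tags), function(nm) {
    items <- as.character(tags[[nm]])
    item_bytes <- do.call(c, c(list(raw(0)), lapply(items, function(it) {
      data <- charToRaw(it)
      # item header: four int32 copies of the payload length
      c(w_uint32(rep(length(data), 4)), csa_pad4(data))
    })))
    c(csa_name64(nm),
      w_uint32(length(items)),      # vm
      c(charToRaw("LO"), raw(2)),   # vr, padded to 4
      w_uint32(0),                  # syngodt
      w_uint32(length(items)),      # nitems
      w_uint32(77),
      item_bytes)
  })))
  header <- c(w_uint32(length(tags)), w_uint32(77))
  if (dialect == "CSA2") {
    c(charToRaw("SV10"), as.raw(c(4, 3, 2, 1)), header, body)
  } else {
    c(header, body)
  }
}

#' @noRd
csa_parse <- function(bytes) {
  cur <- dcm_cursor(bytes)
  dialect <- "CSA1"
  if (length(bytes) >= 4 && identical(rawToChar(bytes[1:4]), "SV10")) {
    dialect <- "CSA2"
    cur_take(cur, 8L, "CSA2 magic")
  }
  n_tags <- cur_uint32(cur, "CSA tag count")
  cur_uint32(cur, "CSA header constant")
  if (n_tags < 0 || n_tags > 1024) {
    abort(sprintf("implausible CSA tag count %d at offset %d.",
                  n_tags, cur$pos - 1L),
          class = "mrsfit_error_dicom_parse")
  }
  out <- list()
  for (i in seq_len(n_tags)) {
    name_raw <- cur_take(cur, 64L, sprintf("CSA tag %d name", i))
    nul <- which(name_raw == 0)[1]
    name <- rawToChar(name_raw[seq_len(if (is.na(nul)) 64L else nul - 1L)])
    cur_uint32(cur, "vm")
    cur_take(cur, 4L, "vr")
    cur_uint32(cur, "syngodt")
    nitems <- cur_uint32(cur, "nitems")
    cur_uint32(cur, "tag constant")
    items <- character(0)
    for (j in seq_len(nitems)) {
      lens <- vapply(1:4, function(k) cur_uint32(cur, "item length"), numeric(1))
      # CSA2 stores the payload length in the second slot; CSA1 in the
      # first. The fixture writer sets all four equal, so either works;
      # for foreign files pick by dialect.
      len <- if (dialect == "CSA2") lens[2] else lens[1]
      data <- cur_take(cur, len, sprintf("CSA tag '%s' item %d", name, j))
      pad <- (4 - len %% 4) %% 4
      if (pad > 0) cur_take(cur, pad, "item padding")
      items <- c(items, rawToChar(data[data != as.raw(0)]))
    }
    out[[name]] <- items
  }
  attr(out, "dialect") <- dialect
  out
}

csa_num <- function(csa, name, default = NULL) {
  v <- csa[[name]]
  if (is.null(v) || length(v) == 0) return(default)
  as.numeric(v[1])
}
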