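# Minimal DICOM explicit-VR little-endian codec.
#
# Covers exactly the attribute subset needed to read and write RT Plan and
# RT Structure Set objects for plan-check purposes. It is not a general
# DICOM implementation: one transfer syntax (Explicit VR Little Endian),
# no pixel data, no charset handling beyond ASCII.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
# Org root reserved for locally generated (synthetic) instances.
UID_FIXTURE_ROOT <- "1.2.826.0.1.3680043.9.7435"

.DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.DCM_STRING_VRS <- c(
  "AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO",
  "LT", "PN", "SH", "ST", "TM", "UI", "UT"
)

dcm_el <- function(group, element, vr, value) {
  list(group = as.integer(group), element = as.integer(element), vr = vr, value = value)
}

dcm_tag <- function(group, element) sprintf("%04X%04X", group, element)

.dcm_u16_bytes <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
}

.dcm_u32_bytes <- function(x) {
  # x may exceed .Machine$integer.max only for the undefined-length marker,
  # which is written literally elsewhere; here x < 2^31.
  x <- as.integer(x)
  as.raw(c(
    bitwAnd(x, 255L),
    bitwAnd(bitwShiftR(x, 8L), 255L),
    bitwAnd(bitwShiftR(x, 16L), 255L),
    bitwAnd(bitwShiftR(x, 24L), 255L)
  ))
}

.dcm_format_number <- function(x) {
  # DS values are limited to 16 bytes; %.8g stays well under that for mm/MU.
  sprintf("%.8g", x)
}

.dcm_value_bytes <- function(vr, value) {
  if (vr %in% c("UL", "US")) {
    return(writeBin(as.integer(value), raw(),
      size = if (vr == "UL") 4L else 2L, endian = "little"
    ))
  }
  if (vr %in% c("FL", "FD")) {
    return(writeBin(as.numeric(value), raw(),
      size = if (vr == "FL") 4L else 8L, endian = "little"
    ))
  }
  if (vr == "OB") {
    return(as.raw(value))
  }
  if (vr %in% .DCM_STRING_VRS) {
    if (vr %in% c("DS")) value <- .dcm_format_number(value)
    if (vr %in% c("IS")) value <- sprintf("%d", as.integer(value))
    s <- paste(value, collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L) {
      b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    }
    return(b)
  }
  abort(sprintf("unsupported VR for writing: %s", vr))
}

.dcm_item_bytes <- function(elements) {
  body <- if (length(elements)) {
    do.call(c, lapply(elements, .dcm_element_bytes))
  } else {
    raw(0)
  }
  c(
    as.raw(c(0xfe, 0xff, 0x00, 0xe0)), as.raw(rep(0xff, 4L)), # item, undefined length
    body,
    as.raw(c(0xfe, 0xff, 0x0d, 0xe0)), raw(4L) # item delimitation
  )
}

.dcm_element_bytes <- function(el) {
  header <- c(.dcm_u16_bytes(el$group), .dcm_u16_bytes(el$element), charToRaw(el$vr))
  if (el$vr == "SQ") {
    body <- if (length(el$value)) {
      do.call(c, lapply(el$value, .dcm_item_bytes))
    } else {
      raw(0)
    }
    return(c(
      header, raw(2L), as.raw(rep(0xff, 4L)), # undefined length
      body,
      as.raw(c(0xfe, 0xff, 0xdd, 0xe0)), raw(4L) # sequence delimitation
    ))
  }
  v <- .dcm_value_bytes(el$vr, el$value)
  if (el$vr %in% .DCM_LONG_VRS) {
    c(header, raw(2L), .dcm_u32_bytes(length(v)), v)
  } else {
    c(header, .dcm_u16_bytes(length(v)), v)
  }
}

#' Write a DICOM file (explicit VR little endian)
#'
#' Low-level writer used by the fixture generator. `elements` is a list of
#' `dcm_el()` entries in ascending tag order; the file meta group is
#' assembled here from the SOP class/instance UIDs.
#'
#' @param path Output file path.
#' @param sop_class_uid,sop_instance_uid SOP Class / Instance UIDs.
#' @param elements List of data-set elements built with `dcm_el()`.
#' @return `path`, invisibly.
#' @keywords internal
write_dicom <- function(path, sop_class_uid, sop_instance_uid, elements) {
  meta <- list(
    dcm_el(0x0002, 0x0001, "OB", c(0L, 1L)),
    dcm_el(0x0002, 0x0002, "UI", sop_class_uid),
    dcm_el(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_el(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE),
    dcm_el(0x0002, 0x0012, "UI", paste0(UID_FIXTURE_ROOT, ".1"))
  )
  meta_body <- do.call(c, lapply(meta, .dcm_element_bytes))
  group_len <- .dcm_element_bytes(dcm_el(0x0002, 0x0000, "UL", length(meta_body)))
  body <- do.call(c, lapply(elements, .dcm_element_bytes))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), group_len, meta_body, body), con)
  invisible(path)
}

# ---- reading ----------------------------------------------------------------

.dcm_state <- function(bytes) {
  st <- new.env(parent = emptyenv())
  st$b <- bytes
  st$pos <- 1L
  st
}

.dcm_read_u16 <- function(st) {
  v <- as.integer(st$b[st$pos]) + 256L * as.integer(st$b[st$pos + 1L])
  st$pos <- st$pos + 2L
  v
}

.dcm_read_u32 <- function(st) {
  # numeric, so the undefined-length marker 0xFFFFFFFF survives
  v <- sum(as.numeric(st$b[st$pos:(st$pos + 3L)]) * c(1, 256, 65536, 16777216))
  st$pos <- st$pos + 4L
  v
}

# drop trailing padding (space or nul) before decoding text
.dcm_text <- function(data) {
  while (length(data) && data[length(data)] %in% as.raw(c(0L, 32L))) {
    data <- data[-length(data)]
  }
  rawToChar(data)
}

.dcm_convert <- function(vr, data) {
  if (vr %in% c("UL", "US")) {
    return(readBin(data, integer(),
      n = length(data) / (if (vr == "UL") 4L else 2L),
      size = if (vr == "UL") 4L else 2L, endian = "little",
      signed = vr == "UL"
    ))
  }
  if (vr %in% c("FL", "FD")) {
    return(readBin(data, numeric(),
      n = length(data) / (if (vr == "FL") 4L else 8L),
      size = if (vr == "FL") 4L else 8L, endian = "little"
    ))
  }
  if (vr %in% c("OB", "OW", "UN")) {
    return(data)
  }
  s <- .dcm_text(data)
  parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  if (vr == "DS") {
    return(as.numeric(parts))
  }
  if (vr == "IS") {
    return(as.integer(parts))
  }
  if (length(parts) == 0L) "" else parts
}

.dcm_parse_sequence <- function(st, len) {
  items <- list()
  end_pos <- if (len >= 4294967295) NA_integer_ else st$pos + len
  repeat {
    if (!is.na(end_pos) && st$pos >= end_pos) break
    if (st$pos > length(st$b)) abort("truncated DICOM sequence")
    g <- .dcm_read_u16(st)
    e <- .dcm_read_u16(st)
    ilen <- .dcm_read_u32(st)
    if (g == 0xFFFE && e == 0xE0DD) break # sequence delimitation
    if (!(g == 0xFFFE && e == 0xE000)) abort("malformed DICOM sequence item")
    if (ilen >= 4294967295) {
      items[[length(items) + 1L]] <- .dcm_parse_elements(st, NA_integer_, in_item = TRUE)
    } else {
      items[[length(items) + 1L]] <- .dcm_parse_elements(st, st$pos + ilen, in_item = FALSE)
    }
  }
  items
}

.dcm_parse_elements <- function(st, end_pos, in_item = FALSE) {
  out <- list()
  repeat {
    if (!is.na(end_pos) && st$pos >= end_pos) break
    if (st$pos > length(st$b)) {
      if (is.na(end_pos) && !in_item) break
      abort("truncated DICOM stream")
    }
    g <- .dcm_read_u16(st)
    e <- .dcm_read_u16(st)
    if (g == 0xFFFE) {
      if (e == 0xE00D && in_item) { # item delimitation: consume length, done
        .dcm_read_u32(st)
        break
      }
      abort("unexpected delimitation tag in DICOM stream")
    }
    vr <- rawToChar(st$b[st$pos:(st$pos + 1L)])
    st$pos <- st$pos + 2L
    if (vr %in% .DCM_LONG_VRS) {
      st$pos <- st$pos + 2L # reserved
      len <- .dcm_read_u32(st)
    } else {
      len <- .dcm_read_u16(st)
    }
    if (vr == "SQ") {
      value <- .dcm_parse_sequence(st, len)
    } else {
      if (len >= 4294967295) abort("undefined length outside a sequence")
      data <- if (len > 0) st$b[st$pos:(st$pos + len - 1L)] else raw(0)
      st$pos <- st$pos + len
      value <- .dcm_convert(vr, data)
    }
    out[[dcm_tag(g, e)]] <- list(vr = vr, value = value)
  }
  out
}

#' Read a DICOM file into a tag-keyed list
#'
#' Parses an explicit-VR little-endian DICOM file. Returns `list(meta, data)`
#' where both are lists keyed by `GGGGEEEE` tag strings, each entry holding
#' `vr` and a decoded `value` (sequences become lists of such lists).
#'
#' @param path File to read.
#' @return A list with components `meta` and `data`.
#' @keywords internal
read_dicom <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  n <- file.size(path)
  bytes <- readBin(path, raw(), n)
  if (n < 140 || rawToChar(bytes[129:132]) != "DICM") {
    abort(sprintf("not a DICOM file (missing DICM magic): %s", path), class = "apart_format_error")
  }
  st <- .dcm_state(bytes)
  st$pos <- 133L
  # file meta group: group length element tells us where it ends
  g <- .dcm_read_u16(st); e <- .dcm_read_u16(st)
  if (g != 2L || e != 0L) abort("missing file meta group length", class = "apart_format_error")
  vr <- rawToChar(st$b[st$pos:(st$pos + 1L)]); st$pos <- st$pos + 2L
  len <- .dcm_read_u16(st)
  meta_len <- .dcm_convert("UL", st$b[st$pos:(st$pos + len - 1L)])
  st$pos <- st$pos + len
  meta <- .dcm_parse_elements(st, st$pos + meta_len)
  ts <- meta[["00020010"]]$value %||% ""
  if (!identical(ts, UID_EXPLICIT_VR_LE)) {
    abort(sprintf("unsupported transfer syntax: %s", ts), class = "apart_format_error")
  }
  data <- .dcm_parse_elements(st, length(bytes) + 1L)
  list(meta = meta, data = data)
}

.dcm_get <- function(ds, tag, default = NULL) {
  el <- ds[[tag]]
  if (is.null(el)) default else el$value
}
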