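# Minimal DICOM codec: explicit VR little endian only.
#
# Covers exactly what the RT pattern-of-failure workflow needs -- CT image
# storage, RT Structure Set and RT Dose -- with defined-length sequences.
# Strings are ASCII; numeric VRs are parsed to R vectors; SQ values are lists
# of item datasets; OB/OW payloads stay raw. Elements are keyed "GGGG,EEEE".

DCM_TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1" # explicit VR little endian
DCM_SOP_CT      <- "1.2.840.10008.5.1.4.1.1.2"
DCM_SOP_RTDOSE  <- "1.2.840.10008.5.1.4.1.1.481.2"
DCM_SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"

dcm_tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

# UID from the 2.25 (UUID-derived) arc using the current RNG stream, so
# fixture generation is reproducible under a seed.
dcm_new_uid <- function() {
  digits <- c(sample(1:9, 1L), sample(0:9, 30L, replace = TRUE))
  paste0("2.25.", paste(digits, collapse = ""))
}

dcm_element <- function(group, elem, vr, value) {
  list(group = as.integer(group), elem = as.integer(elem),
       vr = vr, value = value)
}

# ---- encoding ---------------------------------------------------------------

dcm_string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                    "PN", "SH", "ST", "TM", "UI", "UT")
dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN") # reserved+32-bit length

dcm_encode_value <- function(vr, value) {
  if (vr %in% dcm_string_vrs) {
    s <- paste(as.character(value), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L)
      b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    return(b)
  }
  switch(vr,
    US = writeBin(as.integer(value), raw(), size = 2L, endian = "little"),
    SS = writeBin(as.integer(value), raw(), size = 2L, endian = "little"),
    UL = writeBin(as.integer(value), raw(), size = 4L, endian = "little"),
    SL = writeBin(as.integer(value), raw(), size = 4L, endian = "little"),
    FL = writeBin(as.numeric(value), raw(), size = 4L, endian = "little"),
    FD = writeBin(as.numeric(value), raw(), size = 8L, endian = "little"),
    OB = ,
    OW = as.raw(value),
    SQ = {
      items <- lapply(value, function(item) {
        body <- dcm_encode_dataset(item)
        c(writeBin(c(0xFFFEL, 0xE000L), raw(), size = 2L, endian = "little"),
          writeBin(length(body), raw(), size = 4L, endian = "little"),
          body)
      })
      do.call(c, c(items, list(raw(0))))
    },
    stop("unsupported VR for encoding: ", vr)
  )
}

dcm_encode_element <- function(el) {
  body <- dcm_encode_value(el$vr, el$value)
  head <- writeBin(c(el$group, el$elem), raw(), size = 2L, endian = "little")
  if (el$vr %in% dcm_long_vrs) {
    c(head, charToRaw(el$vr), as.raw(c(0L, 0L)),
      writeBin(length(body), raw(), size = 4L, endian = "little"), body)
  } else {
    if (length(body) > 65534L)
      stop("value too long for short-form VR ", el$vr)
    c(head, charToRaw(el$vr),
      writeBin(length(body), raw(), size = 2L, endian = "little"), body)
  }
}

dcm_encode_dataset <- function(elements) {
  do.call(c, c(lapply(elements, dcm_encode_element), list(raw(0))))
}

# Write a complete Part-10 file: preamble, DICM magic, file meta group,
# dataset in explicit VR little endian.
dcm_write_file <- function(path, elements, sop_class_uid, sop_instance_uid) {
  meta_body <- dcm_encode_dataset(list(
    dcm_element(0x0002L, 0x0001L, "OB", as.raw(c(0L, 1L))),
    dcm_element(0x0002L, 0x0002L, "UI", sop_class_uid),
    dcm_element(0x0002L, 0x0003L, "UI", sop_instance_uid),
    dcm_element(0x0002L, 0x0010L, "UI", DCM_TRANSFER_SYNTAX_ELE),
    dcm_element(0x0002L, 0x0012L, "UI", "2.25.730462571891223846131")
  ))
  meta_len <- dcm_encode_element(
    dcm_element(0x0002L, 0x0000L, "UL", length(meta_body)))
  dataset <- dcm_encode_dataset(elements)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_len, meta_body, dataset), con)
  invisible(path)
}

# ---- decoding ---------------------------------------------------------------

dcm_u16 <- function(buf, at) {
  readBin(buf[at:(at + 1L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}
dcm_u32 <- function(buf, at) {
  v <- readBin(buf[at:(at + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

dcm_parse_value <- function(vr, body) {
  if (vr %in% dcm_string_vrs) {
    s <- rawToChar(body[body != as.raw(0L)])
    parts <- trimws(strsplit(s, "\\", fixed = TRUE)[[1L]])
    return(switch(vr,
                  DS = as.numeric(parts),
                  IS = as.integer(parts),
                  parts))
  }
  switch(vr,
    US = readBin(body, "integer", n = length(body) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    SS = readBin(body, "integer", n = length(body) / 2L, size = 2L,
                 signed = TRUE, endian = "little"),
    UL = ,
    SL = readBin(body, "integer", n = length(body) / 4L, size = 4L,
                 endian = "little"),
    FL = readBin(body, "numeric", n = length(body) / 4L, size = 4L,
                 endian = "little"),
    FD = readBin(body, "numeric", n = length(body) / 8L, size = 8L,
                 endian = "little"),
    body # OB/OW/UN stay raw
  )
}

# parse a dataset from buf[from..to]; returns named list keyed "GGGG,EEEE"
dcm_parse_dataset <- function(buf, from, to) {
  out <- list()
  at <- from
  while (at + 7L <= to + 1L) {
    group <- dcm_u16(buf, at); elem <- dcm_u16(buf, at + 2L)
    if (group == 0xFFFEL) { # delimitation items inside undefined-length SQ
      len <- dcm_u32(buf, at + 4L)
      at <- at + 8L + if (elem == 0xE000L) 0L else 0L
      if (elem == 0xE0DDL || elem == 0xE00DL) next
      stop("unexpected item tag outside sequence parsing")
    }
    vr <- rawToChar(buf[(at + 4L):(at + 5L)])
    if (vr %in% dcm_long_vrs) {
      len <- dcm_u32(buf, at + 8L)
      body_at <- at + 12L
    } else {
      len <- dcm_u16(buf, at + 6L)
      body_at <- at + 8L
    }
    key <- dcm_tag_key(group, elem)
    if (vr == "SQ") {
      out[[key]] <- dcm_parse_sequence(buf, body_at, len)
      at <- if (len == 4294967295) attr(out[[key]], "end") else body_at + len
      attr(out[[key]], "end") <- NULL
    } else {
      if (len == 4294967295)
        stop("undefined length on non-SQ element ", key)
      body <- if (len > 0L) buf[body_at:(body_at + len - 1L)] else raw(0L)
      out[[key]] <- dcm_parse_value(vr, body)
      at <- body_at + len
    }
  }
  out
}

dcm_parse_sequence <- function(buf, at, len) {
  items <- list()
  end <- if (len == 4294967295) length(buf) else at + len - 1L
  while (at + 7L <= end + 1L) {
    group <- dcm_u16(buf, at); elem <- dcm_u16(buf, at + 2L)
    ilen <- dcm_u32(buf, at + 4L)
    at <- at + 8L
    if (group == 0xFFFEL && elem == 0xE0DDL) break # sequence delimiter
    if (!(group == 0xFFFEL && elem == 0xE000L))
      stop("malformed sequence item tag")
    if (ilen == 4294967295)
      stop("undefined-length items not supported")
    items[[length(items) + 1L]] <- dcm_parse_dataset(buf, at, at + ilen - 1L)
    at <- at + ilen
  }
  attr(items, "end") <- at
  items
}

# Read a Part-10 DICOM file into a flat named list (sequences nested).
dcm_read_file <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  # file meta group is always explicit VR little endian
  at <- 133L
  meta_end <- length(buf)
  first <- dcm_parse_dataset_until(buf, at)
  meta <- first$dataset
  ts <- meta[["0002,0010"]]
  if (is.null(ts) || ts != DCM_TRANSFER_SYNTAX_ELE)
    stop("unsupported transfer syntax: ", if (is.null(ts)) "<missing>" else ts)
  ds <- dcm_parse_dataset(buf, first$at, length(buf))
  attr(ds, "meta") <- meta
  ds
}

# parse consecutive group-0002 elements, return dataset + position after them
dcm_parse_dataset_until <- function(buf, at) {
  out <- list()
  while (at + 7L <= length(buf)) {
    group <- dcm_u16(buf, at)
    if (group != 0x0002L) break
    elem <- dcm_u16(buf, at + 2L)
    vr <- rawToChar(buf[(at + 4L):(at + 5L)])
    if (vr %in% dcm_long_vrs) {
      len <- dcm_u32(buf, at + 8L); body_at <- at + 12L
    } else {
      len <- dcm_u16(buf, at + 6L); body_at <- at + 8L
    }
    body <- if (len > 0L) buf[body_at:(body_at + len - 1L)] else raw(0L)
    out[[dcm_tag_key(group, elem)]] <- dcm_parse_value(vr, body)
    at <- body_at + len
  }
  list(dataset = out, at = at)
}

dcm_get <- function(ds, key, default = NULL) {
  v <- ds[[key]]
  if (is.null(v)) default else v
}

dcm_require <- function(ds, key, what) {
  v <- ds[[key]]
  if (is.null(v)) stop("DICOM element missing: ", key, " (", what, ")")
  v
}

# decode 16-bit pixel payload (raw) to integer vector
dcm_decode_pixels16 <- function(body, signed) {
  readBin(body, "integer", n = length(body) / 2L, size = 2L,
          signed = signed, endian = "little")
}

dcm_encode_pixels16 <- function(values, signed) {
  values <- as.integer(round(values))
  lim <- if (signed) c(-32768L, 32767L) else c(0L, 65535L)
  if (any(values < lim[1L] | values > lim[2L]))
    stop("pixel values out of 16-bit range")
  if (!signed) values <- ifelse(values > 32767L, values - 65536L, values)
  writeBin(values, raw(), size = 2L, endian = "little")
}
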