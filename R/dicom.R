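# Minimal DICOM file support: explicit VR little endian, one single-frame
# monochrome image per file.  Covers exactly the geometry and pixel tags the
# phantom pipeline needs; it is a purpose-built writer/reader pair, not a
# general DICOM implementation.

.uid_root <- "1.2.826.0.1.3680043.10.424"
.ts_explicit_le <- "1.2.840.10008.1.2.1"

.short_vrs <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS",
                "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL",
                "US")

.u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                               endian = "little")
.u32le <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                               endian = "little")

.dcm_string_raw <- function(value, pad = as.raw(0x20)) {
  r <- charToRaw(paste(value, collapse = "\\"))
  if (length(r) %% 2L == 1L) r <- c(r, pad)
  r
}

.dcm_ds <- function(x) paste(formatC(x, digits = 10, format = "g"),
                             collapse = "\\")

# one data element, explicit VR little endian
.dcm_element <- function(group, elem, vr, value) {
  if (vr %in% c("UI")) {
    val <- .dcm_string_raw(value, pad = as.raw(0x00))
  } else if (vr %in% c("CS", "DS", "IS", "LO", "SH")) {
    val <- .dcm_string_raw(value)
  } else if (vr == "US") {
    val <- .u16le(value)
  } else if (vr == "UL") {
    val <- .u32le(value)
  } else if (vr %in% c("OB", "OW")) {
    val <- value  # already raw
  } else {
    stop("unsupported VR: ", vr)
  }
  hdr <- c(.u16le(group), .u16le(elem), charToRaw(vr))
  if (vr %in% .short_vrs) {
    c(hdr, .u16le(length(val)), val)
  } else {
    c(hdr, as.raw(c(0, 0)), .u32le(length(val)), val)
  }
}

# write one slice; pixels is an integer vector in row-major order (column
# index, i.e. the x voxel axis, varying fastest)
.dcm_write_slice <- function(path, pixels, rows, cols, modalityCode,
                             ipp, iop, pixelSpacingRowCol, sliceThickness,
                             instanceNumber, seriesUid, studyUid, forUid,
                             signedPixels, rescaleIntercept, rescaleSlope) {
  sopClass <- if (modalityCode == "CT") "1.2.840.10008.5.1.4.1.1.2"
              else "1.2.840.10008.5.1.4.1.1.128"
  sopUid <- paste0(seriesUid, ".", instanceNumber)

  stored <- as.integer(round(pixels))
  if (signedPixels) {
    if (any(stored < -32768L | stored > 32767L))
      stop("pixel values out of int16 range")
  } else {
    if (any(stored < 0L | stored > 65535L))
      stop("pixel values out of uint16 range")
    stored <- ifelse(stored > 32767L, stored - 65536L, stored)
  }
  pixraw <- writeBin(stored, raw(), size = 2L, endian = "little")

  meta <- c(
    .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    .dcm_element(0x0002, 0x0002, "UI", sopClass),
    .dcm_element(0x0002, 0x0003, "UI", sopUid),
    .dcm_element(0x0002, 0x0010, "UI", .ts_explicit_le),
    .dcm_element(0x0002, 0x0012, "UI", paste0(.uid_root, ".1")))
  meta <- c(.dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)

  body <- c(
    .dcm_element(0x0008, 0x0016, "UI", sopClass),
    .dcm_element(0x0008, 0x0018, "UI", sopUid),
    .dcm_element(0x0008, 0x0060, "CS", modalityCode),
    .dcm_element(0x0018, 0x0050, "DS", .dcm_ds(sliceThickness)),
    .dcm_element(0x0020, 0x000D, "UI", studyUid),
    .dcm_element(0x0020, 0x000E, "UI", seriesUid),
    .dcm_element(0x0020, 0x0013, "IS", as.character(instanceNumber)),
    .dcm_element(0x0020, 0x0032, "DS", .dcm_ds(ipp)),
    .dcm_element(0x0020, 0x0037, "DS", .dcm_ds(iop)),
    .dcm_element(0x0020, 0x0052, "UI", forUid),
    .dcm_element(0x0028, 0x0002, "US", 1L),
    .dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_element(0x0028, 0x0010, "US", rows),
    .dcm_element(0x0028, 0x0011, "US", cols),
    .dcm_element(0x0028, 0x0030, "DS", .dcm_ds(pixelSpacingRowCol)),
    .dcm_element(0x0028, 0x0100, "US", 16L),
    .dcm_element(0x0028, 0x0101, "US", 16L),
    .dcm_element(0x0028, 0x0102, "US", 15L),
    .dcm_element(0x0028, 0x0103, "US", if (signedPixels) 1L else 0L),
    .dcm_element(0x0028, 0x1052, "DS", .dcm_ds(rescaleIntercept)),
    .dcm_element(0x0028, 0x1053, "DS", .dcm_ds(rescaleSlope)),
    .dcm_element(0x7FE0, 0x0010, "OW", pixraw))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# parse one DICOM file written in explicit VR little endian; returns the
# tags the pipeline needs plus the raw pixel vector
.dcm_read_file <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 140L || rawToChar(r[129:132]) != "DICM")
    stop(.nemaiq_error("malformedSeries",
                       sprintf("%s: not a DICOM part-10 file", path)))
  pos <- 133L
  tags <- list()
  u16 <- function(at) readBin(r[at + 0:1], "integer", size = 2L,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(r[at + 0:3], "integer", size = 4L,
                              endian = "little")
  repeat {
    if (pos + 7L > length(r)) break
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(r[pos + 4:5])
    if (vr %in% .short_vrs) {
      len <- u16(pos + 6L); vstart <- pos + 8L
    } else {
      len <- u32(pos + 8L); vstart <- pos + 12L
    }
    key <- sprintf("%04X%04X", group, elem)
    val <- r[vstart + seq_len(len) - 1L]
    if (group != 0x0002L) {
      tags[[key]] <- list(vr = vr, raw = val)
      if (group == 0x7FE0L && elem == 0x0010L) break
    }
    pos <- vstart + len
  }
  getstr <- function(key) {
    el <- tags[[key]]
    if (is.null(el)) return(NULL)
    trimws(rawToChar(el$raw[el$raw != as.raw(0)]))
  }
  getnum <- function(key) {
    s <- getstr(key)
    if (is.null(s)) NULL else as.numeric(strsplit(s, "\\\\")[[1]])
  }
  getu16 <- function(key) {
    el <- tags[[key]]
    if (is.null(el)) NULL
    else readBin(el$raw, "integer", size = 2L, signed = FALSE,
                 endian = "little")
  }
  pixel <- tags[["7FE00010"]]
  req <- list(modality = getstr("00080060"), ipp = getnum("00200032"),
              iop = getnum("00200037"), rows = getu16("00280010"),
              cols = getu16("00280011"), pixelSpacing = getnum("00280030"))
  if (any(vapply(req, is.null, logical(1))) || is.null(pixel))
    stop(.nemaiq_error("malformedSeries",
                       sprintf("%s: missing required geometry tags", path)))
  signed <- identical(getu16("00280103"), 1L)
  px <- readBin(pixel$raw, "integer", n = length(pixel$raw) / 2L, size = 2L,
                signed = TRUE, endian = "little")
  if (!signed) px <- ifelse(px < 0L, px + 65536L, px)
  slope <- getnum("00281053"); icpt <- getnum("00281052")
  vals <- px * (if (is.null(slope)) 1 else slope) +
    (if (is.null(icpt)) 0 else icpt)
  c(req, list(sliceThickness = getnum("00180050"), values = vals,
              instance = getstr("00200013")))
}
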