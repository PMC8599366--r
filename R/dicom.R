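## Minimal DICOM support: enough to ingest an axial CT series for slicing.
## Scope: single-frame, uncompressed, explicit-VR little-endian files with
## identity in-plane orientation (1\0\0\0\1\0). This is the format the
## package's own fixture writer emits; anything else is rejected with a
## format error. Full DICOM (implicit VR, compressed transfer syntaxes,
## oblique orientations, RT structure sets) is out of scope.

.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.readDicomFile <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    .eusStop("eus_format_error", "'%s' lacks a DICM preamble", path)
  pos <- 133L
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2L,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(raw[at:(at + 3L)], "integer", size = 4L,
                              endian = "little")
  tags <- list()
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      .eusStop("eus_format_error",
               "'%s': implicit-VR or corrupt element at byte %d", path, pos)
    if (vr %in% .LONG_VRS) {
      len <- u32(pos + 8L); data <- pos + 12L
    } else {
      len <- u16(pos + 6L); data <- pos + 8L
    }
    if (len < 0 || data + len - 1L > length(raw) + 1L)
      .eusStop("eus_format_error", "'%s': element overruns file", path)
    key <- sprintf("%04X,%04X", group, elem)
    bytes <- if (len > 0) raw[data:(data + len - 1L)] else raw(0)
    tags[[key]] <- list(vr = vr, bytes = bytes)
    pos <- data + len
    if (key == "7FE0,0010") break
  }
  tags
}

.dcmNum <- function(tags, key, default = NULL) {
  t <- tags[[key]]
  if (is.null(t)) {
    if (is.null(default))
      .eusStop("eus_format_error", "required DICOM tag (%s) missing", key)
    return(default)
  }
  if (t$vr %in% c("US", "SS"))
    readBin(t$bytes, "integer", n = length(t$bytes) / 2L, size = 2L,
            signed = t$vr == "SS", endian = "little")
  else
    as.numeric(strsplit(trimws(rawToChar(t$bytes)), "\\\\")[[1]])
}

.readDicomSeries <- function(dir) {
  if (!dir.exists(dir))
    .eusStop("eus_input_error", "no such directory: %s", dir)
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE))
  if (length(files) < 2L)
    .eusStop("eus_input_error", "'%s' holds fewer than 2 .dcm files", dir)
  slices <- lapply(files, function(f) {
    tags <- .readDicomFile(f)
    rows <- .dcmNum(tags, "0028,0010"); cols <- .dcmNum(tags, "0028,0011")
    ps <- .dcmNum(tags, "0028,0030")        # (row, col) spacing
    ipp <- .dcmNum(tags, "0020,0032")
    orient <- .dcmNum(tags, "0020,0037", default = c(1, 0, 0, 0, 1, 0))
    if (max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-6)
      .eusStop("eus_format_error", "'%s': only identity orientation supported", f)
    bits <- .dcmNum(tags, "0028,0100", default = 16)
    if (bits != 16)
      .eusStop("eus_format_error", "'%s': only 16-bit pixel data supported", f)
    px <- tags[["7FE0,0010"]]
    if (is.null(px))
      .eusStop("eus_format_error", "'%s': no pixel data", f)
    vals <- readBin(px$bytes, "integer", n = rows * cols, size = 2L,
                    signed = FALSE, endian = "little")
    slope <- .dcmNum(tags, "0028,1053", default = 1)
    icpt <- .dcmNum(tags, "0028,1052", default = 0)
    ## DICOM pixel data is row-major (rows = y, cols = x)
    m <- matrix(vals * slope + icpt, nrow = rows, ncol = cols, byrow = TRUE)
    list(values = t(m), z = ipp[3], xy0 = ipp[1:2], spacing = rev(ps))
  })
  z <- vapply(slices, `[[`, 0, "z")
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  dz <- diff(z)
  if (any(dz <= 0))
    .eusStop("eus_format_error", "duplicate slice positions in '%s'", dir)
  ref <- stats::median(dz)
  if (any(abs(dz - ref) > 0.01 * ref))
    .eusStop("eus_format_error",
             "inconsistent DICOM slice spacing in '%s' (gap %.3g vs %.3g mm; missing slice?)",
             dir, max(dz), ref)
  vals <- vapply(slices, `[[`, slices[[1]]$values, "values")
  Volume3D(vals, spacing = c(slices[[1]]$spacing, ref),
           origin = c(slices[[1]]$xy0, z[1]))
}

## ---- fixture writer (internal; used by the test suite) --------------------

.dcmElement <- function(group, elem, vr, bytes) {
  if (length(bytes) %% 2L == 1L)
    bytes <- c(bytes, if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" "))
  head <- writeBin(c(group, elem), raw(), size = 2L, endian = "little")
  if (vr %in% .LONG_VRS)
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(bytes), raw(), size = 4L, endian = "little"), bytes)
  else
    c(head, charToRaw(vr),
      writeBin(length(bytes), raw(), size = 2L, endian = "little"), bytes)
}

.dcmDS <- function(v) charToRaw(paste(sprintf("%.10g", v), collapse = "\\"))
.dcmUS <- function(v) writeBin(as.integer(v), raw(), size = 2L, endian = "little")

## Writes vol as an axial explicit-VR little-endian series, one file per z
## slice. Intensities are rounded and must fit in [0, 32767].
.writeDicomSeries <- function(vol, dir) {
  stopifnot(is(vol, "Volume3D"))
  v <- round(vol@values)
  stopifnot(min(v) >= 0, max(v) <= 32767)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(v)
  for (k in seq_len(d[3])) {
    slice <- t(v[, , k])                     # rows = y, cols = x
    px <- writeBin(as.integer(t(slice)), raw(), size = 2L, endian = "little")
    body <- c(
      .dcmElement(0x0002L, 0x0010L, "UI", charToRaw("1.2.840.10008.1.2.1")),
      .dcmElement(0x0018L, 0x0050L, "DS", .dcmDS(vol@spacing[3])),
      .dcmElement(0x0020L, 0x0032L, "DS",
                  .dcmDS(c(vol@origin[1], vol@origin[2],
                           vol@origin[3] + (k - 1) * vol@spacing[3]))),
      .dcmElement(0x0020L, 0x0037L, "DS", .dcmDS(c(1, 0, 0, 0, 1, 0))),
      .dcmElement(0x0028L, 0x0010L, "US", .dcmUS(d[2])),
      .dcmElement(0x0028L, 0x0011L, "US", .dcmUS(d[1])),
      .dcmElement(0x0028L, 0x0030L, "DS",
                  .dcmDS(c(vol@spacing[2], vol@spacing[1]))),
      .dcmElement(0x0028L, 0x0100L, "US", .dcmUS(16L)),
      .dcmElement(0x0028L, 0x0103L, "US", .dcmUS(0L)),
      .dcmElement(0x7FE0L, 0x0010L, "OW", px)
    )
    out <- c(raw(128L), charToRaw("DICM"), body)
    writeBin(out, file.path(dir, sprintf("slice_%04d.dcm", k)))
  }
  invisible(dir)
}
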