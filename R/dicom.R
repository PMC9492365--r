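# Minimal single-frame DICOM (Part-10) support: enough to convert an
# uncompressed grayscale slice to an 8-bit image, and to write such slices
# for round-trip fixtures. Explicit and implicit VR little endian only; no
# installed R package reads DICOM, so this is kept deliberately small.

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Convert a single-frame DICOM slice to an 8-bit grayscale image
#'
#' Reads an uncompressed little-endian DICOM file (explicit or implicit VR),
#' extracts the pixel matrix and min-max scales it to `[0, 255]`. A constant
#' slice maps to all zeros (degenerate range, no division by zero).
#' Multi-frame files are rejected.
#'
#' @param path Path to a `.dcm` file.
#' @return Integer `rows x cols` matrix (0-255).
#' @export
dicom_to_gray <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM Part-10 file: ", path)
  pos <- 133L
  u16 <- function(p) as.integer(raw[p]) + 256L * as.integer(raw[p + 1L])
  u32 <- function(p) u16(p) + 65536 * u16(p + 2L)

  tags <- list()
  transfer <- "1.2.840.10008.1.2.1"
  in_meta <- TRUE
  explicit <- TRUE
  while (pos + 7L <= length(raw)) {
    group <- u16(pos)
    elem <- u16(pos + 2L)
    if (in_meta && group != 2L) {
      in_meta <- FALSE
      explicit <- transfer != "1.2.840.10008.1.2"
      if (transfer %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")) {
        # uncompressed little endian: proceed
      } else stop("unsupported transfer syntax: ", transfer)
    }
    if (in_meta || explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .long_vrs) {
        len <- u32(pos + 8L)
        hdr <- 12L
      } else {
        len <- u16(pos + 6L)
        hdr <- 8L
      }
    } else {
      len <- u32(pos + 4L)
      hdr <- 8L
    }
    body <- if (len > 0L) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- body
    if (key == "0002,0010")
      transfer <- trimws(rawToChar(body))
    if (key == "7fe0,0010") break
    pos <- pos + hdr + len
  }

  need <- function(key, what) {
    if (is.null(tags[[key]])) stop("DICOM misses ", what)
    tags[[key]]
  }
  rd_u16 <- function(b) readBin(b, "integer", 1, size = 2, signed = FALSE,
                                endian = "little")
  if (!is.null(tags[["0028,0008"]])) {
    nframes <- suppressWarnings(as.integer(trimws(rawToChar(tags[["0028,0008"]]))))
    if (!is.na(nframes) && nframes > 1L)
      stop("multi-frame DICOM is not supported (NumberOfFrames = ", nframes, ")")
  }
  rows <- rd_u16(need("0028,0010", "Rows"))
  cols <- rd_u16(need("0028,0011", "Columns"))
  bits <- rd_u16(need("0028,0100", "BitsAllocated"))
  px <- need("7fe0,0010", "PixelData")
  vals <- if (bits == 16L) {
    readBin(px, "integer", rows * cols, size = 2, signed = FALSE,
            endian = "little")
  } else if (bits == 8L) {
    as.integer(px[seq_len(rows * cols)])
  } else stop("unsupported BitsAllocated: ", bits)
  m <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix(0L, rows, cols))
  clip8((m - rng[1]) / (rng[2] - rng[1]) * 255)
}

#' Write a grayscale matrix as a single-frame DICOM file
#'
#' Explicit VR little endian, 16-bit unsigned pixels. Intended for building
#' synthetic round-trip fixtures for [dicom_to_gray()].
#'
#' @param pixels Integer matrix of nonnegative pixel values (< 65536).
#' @param path Output path.
#' @param n_frames NumberOfFrames tag value; values > 1 produce a file that
#'   [dicom_to_gray()] rejects (used to exercise that error path).
#' @return The path, invisibly.
#' @export
write_dicom_gray <- function(pixels, path, n_frames = 1L) {
  stopifnot(is.matrix(pixels), all(pixels >= 0), all(pixels < 65536))
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  elem_short <- function(group, el, vr, body) {
    w16(c(group, el))
    writeChar(vr, con, eos = NULL)
    if (length(body) %% 2L == 1L) body <- c(body, as.raw(0))
    w16(length(body))
    if (length(body)) writeBin(body, con)
  }
  elem_long <- function(group, el, vr, body) {
    w16(c(group, el))
    writeChar(vr, con, eos = NULL)
    w16(0L)
    writeBin(length(body), con, size = 4, endian = "little")
    writeBin(body, con)
  }
  us_body <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                  endian = "little")
  str_body <- function(s) {
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L) b <- c(b, as.raw(0))
    b
  }

  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  ts <- str_body("1.2.840.10008.1.2.1")
  # meta group length = bytes of the transfer-syntax element (8 + payload)
  elem_short(0x0002, 0x0000, "UL",
             writeBin(as.integer(8L + length(ts)), raw(), size = 4,
                      endian = "little"))
  elem_short(0x0002, 0x0010, "UI", ts)

  elem_short(0x0028, 0x0002, "US", us_body(1L))                 # samples/pixel
  if (n_frames != 1L)
    elem_short(0x0028, 0x0008, "IS", str_body(as.character(n_frames)))
  elem_short(0x0028, 0x0010, "US", us_body(nrow(pixels)))
  elem_short(0x0028, 0x0011, "US", us_body(ncol(pixels)))
  elem_short(0x0028, 0x0100, "US", us_body(16L))
  elem_short(0x0028, 0x0101, "US", us_body(16L))
  elem_short(0x0028, 0x0103, "US", us_body(0L))
  px <- writeBin(as.integer(t(pixels)), raw(), size = 2, endian = "little")
  elem_long(0x7FE0, 0x0010, "OW", px)
  invisible(path)
}
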