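# Minimal single-frame DICOM I/O (explicit VR, little endian).
#
# Scope is deliberately narrow: one image frame, uncompressed, explicit-VR
# little-endian transfer syntax, the calibration tags the pipeline needs
# (rescale slope/intercept, pixel spacing, photometric interpretation,
# 8/16-bit signed/unsigned pixel data). Multi-frame files, compressed
# syntaxes and non-image objects are rejected as unsupported.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length.
.vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16 <- function(raw) sum(as.integer(raw) * c(1L, 256L))
.u32 <- function(raw) sum(as.numeric(raw) * c(1, 256, 65536, 16777216))

.raw_u16 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256))
.raw_u32 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256,
                                 x %/% 65536 %% 256, x %/% 16777216 %% 256))

# One explicit-VR element as raw bytes. `value` is raw already.
.dcm_element <- function(group, elem, vr, value) {
  if (length(value) %% 2L == 1L)
    value <- c(value, if (vr %in% c("UI")) as.raw(0L) else charToRaw(" "))
  hdr <- c(.raw_u16(group), .raw_u16(elem), charToRaw(vr))
  if (vr %in% .vr_long) {
    c(hdr, as.raw(c(0L, 0L)), .raw_u32(length(value)), value)
  } else {
    c(hdr, .raw_u16(length(value)), value)
  }
}

.dcm_str <- function(group, elem, vr, s) .dcm_element(group, elem, vr, charToRaw(s))
.dcm_us  <- function(group, elem, x)     .dcm_element(group, elem, "US", .raw_u16(x))

#' Write a minimal single-frame DICOM file (synthetic fixture writer)
#'
#' Writes stored pixel values with the given rescale slope/intercept and
#' calibration tags using the explicit-VR little-endian transfer syntax.
#' Intended for building synthetic test fixtures and phantom exports; it is
#' not a clinical DICOM exporter.
#'
#' @param pixels integer matrix of stored values (pre-rescale), or a
#'   [ct_slice()] whose pixels are stored values.
#' @param path output file path.
#' @param slope,intercept rescale slope/intercept written to the file; real
#'   value = stored * slope + intercept.
#' @param bits bits allocated per pixel, 8 or 16.
#' @param signed logical; write signed (two's complement) stored values.
#' @param photometric `"MONOCHROME2"` (larger = brighter) or `"MONOCHROME1"`.
#' @param pixel_spacing_mm optional (row, col) spacing in mm.
#' @param n_frames number of frames; values other than 1 exist only to build
#'   fixtures that readers must reject.
#' @return the path, invisibly.
#' @export
write_dicom_slice <- function(pixels, path, slope = 1, intercept = 0,
                              bits = 16L, signed = FALSE,
                              photometric = "MONOCHROME2",
                              pixel_spacing_mm = NULL, n_frames = 1L) {
  px <- as_pixels(pixels)
  stopifnot(bits %in% c(8L, 16L))
  if (any(px != round(px)))
    stop("stored DICOM values must be integers", call. = FALSE)
  lim <- if (signed) c(-2^(bits - 1), 2^(bits - 1) - 1) else c(0, 2^bits - 1)
  if (min(px) < lim[1] || max(px) > lim[2])
    stop("stored values exceed the chosen bit depth", call. = FALSE)

  meta_body <- .dcm_str(0x0002, 0x0010, "UI", DICOM_EXPLICIT_LE)
  meta <- c(.dcm_element(0x0002, 0x0000, "UL", .raw_u32(length(meta_body))),
            meta_body)

  vals <- as.vector(t(px))  # DICOM pixel order: row by row
  if (signed) vals <- ifelse(vals < 0, vals + 2^bits, vals)
  pix_raw <- if (bits == 8L) as.raw(vals)
             else as.raw(as.vector(rbind(vals %% 256, vals %/% 256)))
  if (n_frames > 1L) pix_raw <- rep(pix_raw, n_frames)

  ds <- c(
    .dcm_str(0x0008, 0x0060, "CS", "CT"),
    .dcm_us(0x0028, 0x0002, 1L),
    .dcm_str(0x0028, 0x0004, "CS", photometric),
    if (n_frames != 1L) .dcm_str(0x0028, 0x0008, "IS", as.character(n_frames)),
    .dcm_us(0x0028, 0x0010, nrow(px)),
    .dcm_us(0x0028, 0x0011, ncol(px)),
    if (!is.null(pixel_spacing_mm))
      .dcm_str(0x0028, 0x0030, "DS",
               paste(format(pixel_spacing_mm, trim = TRUE), collapse = "\\")),
    .dcm_us(0x0028, 0x0100, bits),
    .dcm_us(0x0028, 0x0101, bits),
    .dcm_us(0x0028, 0x0102, bits - 1L),
    .dcm_us(0x0028, 0x0103, as.integer(signed)),
    .dcm_str(0x0028, 0x1052, "DS", format(intercept, trim = TRUE)),
    .dcm_str(0x0028, 0x1053, "DS", format(slope, trim = TRUE)),
    .dcm_element(0x7FE0, 0x0010, "OW", pix_raw)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 128L)), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

#' Read a single-frame DICOM CT slice
#'
#' Reads an uncompressed explicit-VR little-endian single-frame DICOM image.
#' Rescale slope and intercept are applied when present (the `calibrated`
#' flag records whether they were); pixel spacing is populated from the
#' PixelSpacing tag. MONOCHROME1 images are inverted on load so that larger
#' always means brighter.
#'
#' @param path path to a DICOM file.
#' @return a [ct_slice()].
#' @export
read_dicom_slice <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("unsupported format: not a DICOM file (missing DICM magic): ", path,
         call. = FALSE)

  pos <- 133L
  n <- length(raw)
  tags <- list()
  pixel_raw <- NULL
  syntax <- DICOM_EXPLICIT_LE

  read_str <- function(v) trimws(rawToChar(v[v != as.raw(0L)]))
  while (pos + 7L <= n) {
    group <- .u16(raw[pos:(pos + 1L)])
    elem <- .u16(raw[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported format: implicit-VR or corrupt DICOM element",
           call. = FALSE)
    if (vr %in% .vr_long) {
      len <- .u32(raw[(pos + 8L):(pos + 11L)])
      vstart <- pos + 12L
    } else {
      len <- .u16(raw[(pos + 6L):(pos + 7L)])
      vstart <- pos + 8L
    }
    if (vstart + len - 1L > n)
      stop("unsupported format: truncated DICOM element", call. = FALSE)
    value <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    if (key == "7fe0,0010") {
      pixel_raw <- value
    } else {
      tags[[key]] <- list(vr = vr, value = value)
    }
    if (key == "0002,0010") syntax <- read_str(value)
    pos <- vstart + len
  }

  if (!identical(syntax, DICOM_EXPLICIT_LE))
    stop("unsupported format: transfer syntax ", syntax, call. = FALSE)

  get_str <- function(key) if (is.null(tags[[key]])) NULL else read_str(tags[[key]]$value)
  get_us <- function(key, default = NULL) {
    t <- tags[[key]]
    if (is.null(t)) return(default)
    .u16(t$value[1:2])
  }

  nf <- get_str("0028,0008")
  if (!is.null(nf) && as.integer(nf) != 1L)
    stop("unsupported format: multi-frame DICOM (", nf, " frames)",
         call. = FALSE)
  if (is.null(pixel_raw))
    stop("unsupported format: DICOM object carries no pixel data",
         call. = FALSE)

  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  if (is.null(rows) || is.null(cols))
    stop("unsupported format: missing Rows/Columns", call. = FALSE)
  bits <- get_us("0028,0100", 16L)
  if (!bits %in% c(8L, 16L))
    stop("unsupported format: ", bits, "-bit pixel data", call. = FALSE)
  signed <- identical(get_us("0028,0103", 0L), 1L)
  if (length(pixel_raw) < rows * cols * (bits / 8L))
    stop("unsupported format: pixel data shorter than Rows x Columns",
         call. = FALSE)

  if (bits == 8L) {
    vals <- as.integer(pixel_raw[seq_len(rows * cols)])
  } else {
    m <- matrix(as.integer(pixel_raw[seq_len(2L * rows * cols)]), nrow = 2L)
    vals <- m[1L, ] + 256L * m[2L, ]
  }
  if (signed) vals <- ifelse(vals >= 2^(bits - 1), vals - 2^bits, vals)
  px <- matrix(as.numeric(vals), nrow = rows, ncol = cols, byrow = TRUE)

  slope_s <- get_str("0028,1053"); inter_s <- get_str("0028,1052")
  calibrated <- !is.null(slope_s) || !is.null(inter_s)
  slope <- if (is.null(slope_s)) 1 else as.numeric(slope_s)
  intercept <- if (is.null(inter_s)) 0 else as.numeric(inter_s)
  px <- px * slope + intercept

  photometric <- get_str("0028,0004")
  if (identical(photometric, "MONOCHROME1"))
    px <- max(px) + min(px) - px  # invert so larger = brighter

  spacing <- NULL
  sp_s <- get_str("0028,0030")
  if (!is.null(sp_s)) {
    sp <- as.numeric(strsplit(sp_s, "\\\\")[[1]])
    if (length(sp) == 2L && all(is.finite(sp))) spacing <- sp
  }

  ct_slice(px, pixel_spacing_mm = spacing, source_id = path,
           calibrated = calibrated)
}
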