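#' Read a grayscale PNG or TIFF slice
#'
#' Loads an 8-bit or 16-bit grayscale image losslessly into integer-valued
#' intensities (0..255 or 0..65535). RGB input is converted to luminance
#' (0.299 R + 0.587 G + 0.114 B) with a warning. The `calibrated` flag of the
#' result is always `FALSE`.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return a [ct_slice()].
#' @export
read_image_slice <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      r <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop("cannot read PNG: ",
                                             conditionMessage(e), call. = FALSE))
      depth <- attr(r, "info")$bit.depth
      if (is.null(depth)) depth <- 8L
      r * (2^depth - 1)
    },
    tif = ,
    tiff = {
      r <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                    error = function(e) stop("cannot read TIFF: ",
                                             conditionMessage(e), call. = FALSE))
      r
    },
    stop("unsupported image extension: ", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) {
      warning("RGB image converted to grayscale by luminance")
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]  # gray + alpha: drop alpha
    }
  }
  img <- round(img)
  attributes(img) <- list(dim = dim(img))  # drop reader metadata attributes
  ct_slice(img, source_id = path, calibrated = FALSE)
}

#' Write a binary mask as a PNG file
#'
#' Foreground (1) is written as 255 and background (0) as 0, 8-bit grayscale.
#' [read_mask()] recovers the identical mask.
#'
#' @param mask a [binary_mask()].
#' @param path output `.png` path.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- as_pixels(mask)
  if (!all(m %in% c(0L, 1L))) stop("mask values must be 0/1", call. = FALSE)
  ok <- tryCatch({png::writePNG(m * 1.0, target = path); TRUE},
                 error = function(e) stop("cannot write mask: ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a binary mask from a PNG file
#'
#' Pixels above half intensity are foreground; the complement is background.
#'
#' @param path path to a mask PNG (0/255 by convention).
#' @return a [binary_mask()].
#' @export
read_mask <- function(path) {
  s <- read_image_slice(path)
  mx <- max(s$pixels)
  binary_mask(s$pixels > (if (mx > 0) mx / 2 else 0.5))
}
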