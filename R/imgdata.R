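#' Construct a CT slice
#'
#' A `ct_slice` holds one 2-D grayscale image as a numeric matrix, row-major
#' with the origin at the top-left, plus provenance and calibration metadata.
#' Intensities must be finite; the matrix may carry raw stored values, values
#' rescaled by the DICOM slope/intercept (`calibrated = TRUE`), or normalised
#' values in `[0, 1]`.
#'
#' @param pixels numeric matrix of finite intensities (rows x cols).
#' @param pixel_spacing_mm optional numeric length-2 vector, (row, col)
#'   spacing in millimetres.
#' @param source_id free-text provenance (file path, phantom seed, ...).
#' @param calibrated logical; `TRUE` when rescale slope/intercept have been
#'   applied to the stored values.
#' @return an object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, pixel_spacing_mm = NULL, source_id = "",
                     calibrated = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("slice must have positive height and width", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("all intensities must be finite", call. = FALSE)
  if (!is.null(pixel_spacing_mm)) {
    pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
    if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
      stop("`pixel_spacing_mm` must be two positive numbers", call. = FALSE)
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         pixel_spacing_mm = pixel_spacing_mm,
         source_id = as.character(source_id)[1L],
         calibrated = isTRUE(calibrated)),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d, range [%g, %g], calibrated=%s%s\n",
              x$height, x$width, min(x$pixels), max(x$pixels),
              x$calibrated,
              if (nzchar(x$source_id)) paste0(", source=", x$source_id) else ""))
  invisible(x)
}

#' @export
dim.ct_slice <- function(x) c(x$height, x$width)

#' Construct a binary mask
#'
#' A `binary_mask` is a 2-D grid over \{0, 1\} aligned to a CT slice: a ground
#' truth, a detector's coarse mask, or a refined segmentation.
#'
#' @param values matrix (numeric or logical) containing only 0/1 values.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(values) {
  if (is.logical(values)) {
    v <- values
    storage.mode(v) <- "integer"
    values <- v
  }
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric or logical matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("mask must have positive height and width", call. = FALSE)
  if (!all(values %in% c(0, 1)))
    stop("mask values must be 0 or 1", call. = FALSE)
  storage.mode(values) <- "integer"
  structure(list(values = values, height = nrow(values), width = ncol(values)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground pixels (%.1f%%)\n",
              x$height, x$width, sum(x$values),
              100 * mean(x$values)))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) c(x$height, x$width)

#' Construct a per-pixel probability map
#'
#' Per-pixel lung-membership probabilities in `[0, 1]`, as produced by
#' [estimate_membership_map()].
#'
#' @param values numeric matrix with all entries in `[0, 1]`.
#' @return an object of class `probability_map`.
#' @export
probability_map <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(values)) || min(values) < 0 || max(values) > 1)
    stop("probabilities must be finite and in [0, 1]", call. = FALSE)
  structure(list(values = values, height = nrow(values), width = ncol(values)),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %d x %d, range [%.3f, %.3f]\n",
              x$height, x$width, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.probability_map <- function(x) c(x$height, x$width)

# Coerce to the pixel matrix, accepting the wrapper classes or a bare matrix.
as_pixels <- function(x) {
  if (inherits(x, c("ct_slice"))) x$pixels
  else if (inherits(x, c("binary_mask", "probability_map"))) x$values
  else if (is.matrix(x)) x
  else stop("expected a ct_slice, binary_mask, probability_map or matrix",
            call. = FALSE)
}

check_same_shape <- function(a, b) {
  da <- dim(as_pixels(a)); db <- dim(as_pixels(b))
  if (!identical(da, db))
    stop(sprintf("shape mismatch: %dx%d vs %dx%d", da[1], da[2], db[1], db[2]),
         call. = FALSE)
  invisible(TRUE)
}

#' Normalise slice intensities
#'
#' `minmax` maps the minimum to 0 and the maximum to 1 (a constant image maps
#' to all zeros, keeping downstream density estimation defined). `zscore`
#' centres to mean 0 and scales to (population) standard deviation 1 and
#' errors on a constant image.
#'
#' @param slice a [ct_slice()].
#' @param mode `"minmax"` or `"zscore"`.
#' @return a new `ct_slice` with transformed pixels (metadata preserved).
#' @export
normalize_intensity <- function(slice, mode = c("minmax", "zscore")) {
  mode <- match.arg(mode)
  px <- as_pixels(slice)
  rng <- range(px)
  if (mode == "minmax") {
    out <- if (rng[1] == rng[2]) array(0, dim(px)) else (px - rng[1]) / diff(rng)
  } else {
    if (rng[1] == rng[2])
      stop("zscore normalisation is undefined for a constant image",
           call. = FALSE)
    out <- (px - mean(px)) / sqrt(mean((px - mean(px))^2))
  }
  dim(out) <- dim(px)
  res <- slice
  if (inherits(slice, "ct_slice")) {
    res$pixels <- out
    res
  } else {
    ct_slice(out)
  }
}
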