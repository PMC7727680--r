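#' Specification of a synthetic thoracic phantom
#'
#' Describes an axial chest-CT-like test image: a bright elliptical body on a
#' dark background, two dark elliptical lung fields with bright vessel-like
#' inclusions, and additive Gaussian noise (clipped at 0). Intensities follow
#' the stored-value scale of 16-bit CT without claiming Hounsfield accuracy:
#' the contrast ordering background < lung < vessels < body is what matters.
#' The default contrast satisfies `mu_body - mu_lung >= 4 * sigma_noise`, the
#' separation the boundary refinement relies on.
#'
#' @param image_size side length in pixels (square image), at least 64.
#' @param body_axes,lung_axes ellipse semi-axes in pixels, (row, col) order.
#'   Defaults scale with `image_size`.
#' @param lung_offset lateral displacement of each lung centre from the body
#'   centre, in pixels.
#' @param mu_background,mu_body,mu_lung mean intensities of the three tissue
#'   classes.
#' @param sigma_noise standard deviation of the additive Gaussian noise.
#' @param n_vessels number of bright elliptical inclusions per lung.
#' @param vessel_intensity mean intensity of the inclusions.
#' @param seed RNG seed; all generation is bit-reproducible given the seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 128L,
                         body_axes = round(image_size * c(0.33, 0.42)),
                         lung_axes = round(image_size * c(0.22, 0.13)),
                         lung_offset = round(image_size * 0.18),
                         mu_background = 0, mu_body = 1100, mu_lung = 250,
                         sigma_noise = 40, n_vessels = 3L,
                         vessel_intensity = 1000, seed = 0L) {
  image_size <- as.integer(image_size)
  if (image_size < 64L) stop("image_size must be >= 64", call. = FALSE)
  if (mu_body - mu_lung < 4 * sigma_noise)
    stop("contrast assumption violated: need mu_body - mu_lung >= 4*sigma_noise",
         call. = FALSE)
  ctr <- (image_size + 1) / 2
  if (ctr + body_axes[1] > image_size || ctr + body_axes[2] > image_size ||
      ctr - body_axes[1] < 1 || ctr - body_axes[2] < 1)
    stop("body ellipse overlaps the image border", call. = FALSE)
  if (ctr + lung_axes[1] > image_size ||
      ctr + lung_offset + lung_axes[2] > image_size ||
      ctr - lung_offset - lung_axes[2] < 1)
    stop("lung ellipses overlap the image border", call. = FALSE)
  structure(list(image_size = image_size, body_axes = as.numeric(body_axes),
                 lung_axes = as.numeric(lung_axes),
                 lung_offset = as.numeric(lung_offset),
                 mu_background = mu_background, mu_body = mu_body,
                 mu_lung = mu_lung, sigma_noise = sigma_noise,
                 n_vessels = as.integer(n_vessels),
                 vessel_intensity = vessel_intensity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Logical matrix of pixels whose centre lies inside the ellipse
# ((r - cr)/a)^2 + ((c - cc)/b)^2 <= 1, with (a, b) = (row, col) semi-axes.
ellipse_mask <- function(n_row, n_col, center, axes) {
  r <- matrix(seq_len(n_row), n_row, n_col)
  cc <- matrix(seq_len(n_col), n_row, n_col, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((cc - center[2]) / axes[2])^2 <= 1
}

.phantom_geometry <- function(spec) {
  n <- spec$image_size
  ctr <- (n + 1) / 2
  body <- ellipse_mask(n, n, c(ctr, ctr), spec$body_axes)
  lungL <- ellipse_mask(n, n, c(ctr, ctr - spec$lung_offset), spec$lung_axes)
  lungR <- ellipse_mask(n, n, c(ctr, ctr + spec$lung_offset), spec$lung_axes)
  list(body = body, lungs = lungL | lungR,
       centers = rbind(c(ctr, ctr - spec$lung_offset),
                       c(ctr, ctr + spec$lung_offset)))
}

# Draw vessel-like bright inclusions strictly inside each lung ellipse.
.phantom_vessels <- function(spec, geom) {
  n <- spec$image_size
  vess <- matrix(FALSE, n, n)
  if (spec$n_vessels < 1L) return(vess)
  for (li in 1:2) {
    ctr <- geom$centers[li, ]
    for (v in seq_len(spec$n_vessels)) {
      # polar position well inside the lung; radius 1.5-3 px
      rho <- sqrt(runif(1)) * 0.6
      th <- runif(1, 0, 2 * pi)
      vc <- c(ctr[1] + rho * spec$lung_axes[1] * sin(th),
              ctr[2] + rho * spec$lung_axes[2] * cos(th))
      vr <- runif(1, 1.5, 3)
      vess <- vess | ellipse_mask(n, n, vc, c(vr, vr))
    }
  }
  vess
}

#' Generate a synthetic lung-bearing CT slice with exact ground truth
#'
#' Deterministic given `spec$seed`. The ground-truth mask is the union of the
#' two lung ellipses; vessel inclusions lie inside it and remain part of the
#' lung (the target is the whole lung field, not the air alone).
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `slice` ([ct_slice()]) and `mask`
#'   ([binary_mask()], the ground truth).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  local_seed(spec$seed, {
    geom <- .phantom_geometry(spec)
    vess <- .phantom_vessels(spec, geom)
    n <- spec$image_size
    img <- matrix(spec$mu_background, n, n)
    img[geom$body] <- spec$mu_body
    img[geom$lungs] <- spec$mu_lung
    img[vess & geom$lungs] <- spec$vessel_intensity
    if (spec$sigma_noise > 0)
      img <- pmax(img + matrix(rnorm(n * n, 0, spec$sigma_noise), n, n), 0)
    list(slice = ct_slice(img, source_id = sprintf("phantom(seed=%d)", spec$seed)),
         mask = binary_mask(geom$lungs))
  })
}

#' Generate a synthetic non-lung (abdomen-like) slice
#'
#' The same elliptical body with no dark lung fields; bright inclusions are
#' kept so lung presence cannot be inferred from inclusion presence alone.
#' In the noiseless case no body pixel falls below `mu_body - 3*sigma_noise`.
#'
#' @param spec a [phantom_spec()].
#' @return a [ct_slice()].
#' @export
generate_nonlung_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  local_seed(spec$seed + 1L, {
    geom <- .phantom_geometry(spec)
    vess <- .phantom_vessels(spec, geom)
    n <- spec$image_size
    img <- matrix(spec$mu_background, n, n)
    img[geom$body] <- spec$mu_body
    img[vess & geom$body] <- max(spec$vessel_intensity, spec$mu_body)
    if (spec$sigma_noise > 0)
      img <- pmax(img + matrix(rnorm(n * n, 0, spec$sigma_noise), n, n), 0)
    ct_slice(img, source_id = sprintf("phantom-nonlung(seed=%d)", spec$seed))
  })
}

#' Specification of a coarse-mask corruption
#'
#' Emulates the output of an object detector that bounds the lung without
#' hugging its wall: erosion or dilation by a disc, a diagonal shift, or a
#' blocky bounding-box mask.
#'
#' @param mode one of `"erode"`, `"dilate"`, `"shift"`, `"blocky"`.
#' @param magnitude disc radius / shift distance / box shrink, in pixels
#'   (>= 1).
#' @param seed RNG seed (reserved for stochastic corruptions; the four
#'   built-in modes are deterministic).
#' @return an object of class `corruption_spec`.
#' @export
corruption_spec <- function(mode = c("erode", "dilate", "shift", "blocky"),
                            magnitude = 3, seed = 0L) {
  mode <- match.arg(mode)
  if (magnitude < 1) stop("magnitude must be >= 1", call. = FALSE)
  structure(list(mode = mode, magnitude = magnitude, seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Corrupt a ground-truth mask into a detector-like coarse mask
#'
#' @param gt a nonempty [binary_mask()].
#' @param corruption a [corruption_spec()].
#' @return a [binary_mask()]; errors if the corruption empties the mask.
#' @export
corrupt_mask <- function(gt, corruption) {
  stopifnot(inherits(corruption, "corruption_spec"))
  m <- as_pixels(gt)
  if (sum(m) == 0) stop("ground-truth mask is empty", call. = FALSE)
  mag <- corruption$magnitude
  out <- switch(corruption$mode,
    erode = mask_erode(m, mag),
    dilate = mask_dilate(m, mag),
    shift = shift_matrix(m, mag, mag, 0L),
    blocky = {
      idx <- which(m == 1L, arr.ind = TRUE)
      box <- matrix(0L, nrow(m), ncol(m))
      box[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2])] <- 1L
      mask_erode(box, mag)
    })
  if (sum(out) == 0)
    stop("corruption emptied the mask (degenerate output)", call. = FALSE)
  binary_mask(out)
}

#' Generate a labelled phantom dataset for the lung-presence gate
#'
#' Produces `n_lung` lung-bearing and `n_nonlung` non-lung slices whose
#' geometry and intensities are jittered per slice from a seeded RNG, so the
#' classes are realistic rather than copies of one template. Deterministic
#' given `spec$seed`.
#'
#' @param n_lung,n_nonlung class counts (>= 1).
#' @param spec the base [phantom_spec()]; per-slice parameters jitter
#'   around it.
#' @return a list with `slices` (list of [ct_slice()]), `labels` (character,
#'   `"lung"`/`"nonlung"`), `masks` (ground-truth [binary_mask()] for lung
#'   slices, `NULL` otherwise), and `specs` (per-slice [phantom_spec()]s).
#' @export
generate_classification_dataset <- function(n_lung, n_nonlung,
                                            spec = phantom_spec()) {
  stopifnot(n_lung >= 1, n_nonlung >= 1)
  n <- n_lung + n_nonlung
  local_seed(spec$seed, {
    jit <- function(x, p) x * runif(length(x), 1 - p, 1 + p)
    specs <- lapply(seq_len(n), function(i)
      phantom_spec(image_size = spec$image_size,
                   body_axes = jit(spec$body_axes, 0.08),
                   lung_axes = jit(spec$lung_axes, 0.10),
                   lung_offset = jit(spec$lung_offset, 0.06),
                   mu_background = spec$mu_background,
                   mu_body = jit(spec$mu_body, 0.05),
                   mu_lung = jit(spec$mu_lung, 0.08),
                   sigma_noise = spec$sigma_noise,
                   n_vessels = spec$n_vessels,
                   vessel_intensity = jit(spec$vessel_intensity, 0.05),
                   seed = derive_seed(spec$seed, i)))
    labels <- rep(c("lung", "nonlung"), c(n_lung, n_nonlung))
    slices <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      if (labels[i] == "lung") {
        ph <- generate_phantom(specs[[i]])
        slices[[i]] <- ph$slice
        masks[[i]] <- ph$mask
      } else {
        slices[[i]] <- generate_nonlung_phantom(specs[[i]])
        masks[i] <- list(NULL)
      }
    }
    list(slices = slices, labels = labels, masks = masks, specs = specs)
  })
}

#' Write a phantom dataset to disk as PNG images plus a CSV manifest
#'
#' Each slice is normalised to 0-255 and written as an 8-bit grayscale PNG
#' (the gate's features are invariant to this affine rescaling), ground-truth
#' masks as 0/255 PNGs, and a manifest CSV with columns `path`, `mask_path`,
#' `label`, `seed` indexes the set.
#'
#' @param dataset result of [generate_classification_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_phantom_set <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$slices)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- file.path(dir, sprintf("slice_%03d.png", i))
    px <- normalize_intensity(dataset$slices[[i]], "minmax")$pixels
    png::writePNG(px, target = p)
    mp <- ""
    if (!is.null(dataset$masks[[i]])) {
      mp <- file.path(dir, sprintf("slice_%03d_mask.png", i))
      write_mask(dataset$masks[[i]], mp)
    }
    rows[[i]] <- data.frame(path = p, mask_path = mp,
                            label = dataset$labels[i],
                            seed = dataset$specs[[i]]$seed)
  }
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
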