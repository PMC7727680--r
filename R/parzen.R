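#' Kernel specification for Parzen-window estimation
#'
#' The structuring-element (kernel) function used by the density estimate.
#' Two Gaussian normalisation conventions are provided: `"as_printed"`
#' evaluates the form \eqn{[1/((2\pi)^d |C|)] \exp(-\frac12 u' C^{-1} u)},
#' while `"standard"` uses the multivariate-normal constant
#' \eqn{1/((2\pi)^{d/2} |C|^{1/2})}. The two differ only by a global constant,
#' which cancels in the two-class membership ratio, so boundary refinement is
#' identical under either.
#'
#' @param family `"gaussian"`, `"uniform"` (indicator of \eqn{|u_j| \le 1/2}
#'   per axis) or `"triangular"` (product of \eqn{\max(0, 1-|u_j|)}).
#' @param convention `"as_printed"` or `"standard"` (Gaussian only).
#' @param C symmetric positive-definite covariance matrix (Gaussian only);
#'   default identity of dimension `d`.
#' @param d feature dimension.
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("gaussian", "uniform", "triangular"),
                        convention = c("as_printed", "standard"),
                        C = NULL, d = 1L) {
  family <- match.arg(family)
  convention <- match.arg(convention)
  d <- as.integer(d)
  if (d < 1L) stop("dimension must be >= 1", call. = FALSE)
  if (family == "gaussian") {
    if (is.null(C)) C <- diag(d)
    C <- as.matrix(C)
    if (nrow(C) != d || ncol(C) != d) stop("C must be d x d", call. = FALSE)
    .check_spd(C)
  } else C <- NULL
  structure(list(family = family, convention = convention, C = C, d = d),
            class = "kernel_spec")
}

.check_spd <- function(C) {
  if (!isSymmetric(unname(C), tol = 1e-10))
    stop("C must be symmetric positive-definite", call. = FALSE)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("C must be symmetric positive-definite", call. = FALSE)
  invisible(TRUE)
}

#' Gaussian structuring-element function
#'
#' Evaluates the Gaussian kernel at displacement `u`. Under the
#' `"as_printed"` convention the weight is
#' \eqn{[1/((2\pi)^d |C|)] \exp(-\frac12 u' C^{-1} u)}; under `"standard"`
#' the constant is the multivariate-normal \eqn{1/((2\pi)^{d/2}|C|^{1/2})}.
#' The weight is symmetric in \eqn{u \leftrightarrow -u} and strictly
#' decreasing in the Mahalanobis norm of `u`.
#'
#' @param u numeric displacement vector of length `d`.
#' @param C symmetric positive-definite `d x d` covariance; default identity.
#' @param convention `"as_printed"` or `"standard"`.
#' @return a nonnegative scalar weight.
#' @export
gaussian_kernel <- function(u, C = diag(length(u)),
                            convention = c("as_printed", "standard")) {
  convention <- match.arg(convention)
  u <- as.numeric(u)
  if (any(!is.finite(u))) stop("u must be finite", call. = FALSE)
  d <- length(u)
  C <- as.matrix(C)
  .check_spd(C)
  detC <- det(C)
  quad <- drop(crossprod(u, solve(C, u)))
  const <- if (convention == "as_printed") 1 / ((2 * pi)^d * detC)
           else 1 / ((2 * pi)^(d / 2) * sqrt(detC))
  const * exp(-0.5 * quad)
}

# Kernel weight K(u) for one displacement vector, any family.
.kernel_weight <- function(u, kernel) {
  switch(kernel$family,
    gaussian = gaussian_kernel(u, if (is.null(kernel$C)) diag(length(u)) else kernel$C,
                               kernel$convention),
    uniform = as.numeric(all(abs(u) <= 0.5)),
    triangular = prod(pmax(0, 1 - abs(u))))
}

#' Parzen-window density estimate at a query point
#'
#' Computes \eqn{\hat p(z) = \frac{1}{n h^d} \sum_i K\!\left(\frac{z - z_i}{h}\right)}
#' over the sample set, with `K` the configured structuring element. The
#' estimate is invariant under permutation and duplication of the samples and
#' may be exactly 0 for compact-support kernels when the query is far from
#' every sample.
#'
#' @param z numeric query feature vector (length `d`).
#' @param samples numeric vector (1-D) or matrix with one sample per row.
#' @param h positive bandwidth.
#' @param kernel a [kernel_spec()]; default isotropic Gaussian, as-printed.
#' @return a nonnegative density value.
#' @export
parzen_density <- function(z, samples, h = 0.05,
                           kernel = kernel_spec("gaussian", d = length(z))) {
  if (h <= 0) stop("bandwidth h must be positive", call. = FALSE)
  z <- as.numeric(z)
  d <- length(z)
  S <- if (is.matrix(samples)) samples else matrix(as.numeric(samples), ncol = d)
  if (nrow(S) == 0) stop("sample set is empty (n = 0)", call. = FALSE)
  if (ncol(S) != d) stop("samples and query differ in dimension", call. = FALSE)
  w <- vapply(seq_len(nrow(S)),
              function(i) .kernel_weight((z - S[i, ]) / h, kernel),
              numeric(1))
  sum(w) / (nrow(S) * h^d)
}

#' Isotropic Gaussian mixture density estimate
#'
#' Evaluates the smoothed density model
#' \eqn{p(x) = \frac{1}{N (2\pi h)^D} \sum_n \exp\left[-\frac12 (\lVert x - x_n\rVert / h)^2\right]}
#' under the `"as_printed"` convention, or with the isotropic-Gaussian KDE
#' constant \eqn{1/(N (2\pi h^2)^{D/2})} under `"standard"` (for which the 1-D
#' estimate integrates to 1). For `D = 1` the two agree with
#' [parzen_density()] under the matching kernel convention.
#'
#' @param x numeric query vector of length `D`.
#' @param centers numeric vector (1-D) or matrix with one centre per row.
#' @param h positive bandwidth.
#' @param convention `"as_printed"` or `"standard"`.
#' @return a nonnegative density value.
#' @export
gaussian_mixture_density <- function(x, centers, h,
                                     convention = c("as_printed", "standard")) {
  convention <- match.arg(convention)
  if (h <= 0) stop("bandwidth h must be positive", call. = FALSE)
  x <- as.numeric(x)
  D <- length(x)
  S <- if (is.matrix(centers)) centers else matrix(as.numeric(centers), ncol = D)
  if (nrow(S) == 0) stop("centre set is empty", call. = FALSE)
  if (ncol(S) != D) stop("centres and query differ in dimension", call. = FALSE)
  d2 <- rowSums((S - matrix(x, nrow(S), D, byrow = TRUE))^2)
  const <- if (convention == "as_printed") 1 / (nrow(S) * (2 * pi * h)^D)
           else 1 / (nrow(S) * (2 * pi * h^2)^(D / 2))
  const * sum(exp(-0.5 * d2 / h^2))
}

#' Parzen refinement configuration
#'
#' All tunables of the boundary-refinement stage. Bandwidth `h` is in
#' normalised-intensity units (the slice is min-max normalised to `[0, 1]`
#' before estimation); `shrink_radius` is the disc radius by which the coarse
#' mask is eroded into the seed; `tau` is the membership threshold deciding
#' whether a frontier pixel joins the region (ties `p == tau` count as
#' inside); iteration stops when at most `stability_tolerance` pixels change
#' in one pass or after `max_iterations` passes.
#'
#' @param h bandwidth, positive.
#' @param kernel a [kernel_spec()].
#' @param feature_mode `"intensity"` (1-D) or `"intensity_xy"` (intensity plus
#'   scaled pixel coordinates).
#' @param spatial_scale coordinate scale for `"intensity_xy"`; default
#'   `1/image side` at estimation time.
#' @param shrink_radius seed erosion radius in pixels, >= 0.
#' @param tau decision threshold in (0, 1).
#' @param max_iterations maximum boundary passes, >= 1.
#' @param stability_tolerance maximum changed pixels per pass to declare
#'   convergence.
#' @param sample_cap maximum samples per class (seeded subsampling), >= 100.
#' @param seed RNG seed for the subsampling.
#' @param fill_holes fill interior holes (e.g. vessels) in the final mask.
#' @param reestimate re-estimate the membership map from the current region at
#'   every pass instead of once from the seed.
#' @return an object of class `parzen_config`.
#' @export
parzen_config <- function(h = 0.05, kernel = kernel_spec("gaussian", d = 1L),
                          feature_mode = c("intensity", "intensity_xy"),
                          spatial_scale = NULL, shrink_radius = 3L, tau = 0.5,
                          max_iterations = 100L, stability_tolerance = 0L,
                          sample_cap = 5000L, seed = 0L, fill_holes = TRUE,
                          reestimate = FALSE) {
  feature_mode <- match.arg(feature_mode)
  if (h <= 0) stop("h must be positive", call. = FALSE)
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)", call. = FALSE)
  if (shrink_radius < 0) stop("shrink_radius must be >= 0", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (sample_cap < 100) stop("sample_cap must be >= 100", call. = FALSE)
  structure(list(h = h, kernel = kernel, feature_mode = feature_mode,
                 spatial_scale = spatial_scale,
                 shrink_radius = as.integer(shrink_radius), tau = tau,
                 max_iterations = as.integer(max_iterations),
                 stability_tolerance = as.integer(stability_tolerance),
                 sample_cap = as.integer(sample_cap), seed = as.integer(seed),
                 fill_holes = isTRUE(fill_holes),
                 reestimate = isTRUE(reestimate)),
            class = "parzen_config")
}

#' Shrink a mask by disc erosion
#'
#' Morphological erosion by the exact disc
#' \eqn{\{(dr, dc) : dr^2 + dc^2 \le r^2\}}; radius 0 is the identity. Used to
#' pull a coarse detector mask inward so its interior can seed the foreground
#' intensity model.
#'
#' @param mask a nonempty [binary_mask()].
#' @param radius erosion radius in pixels.
#' @return a [binary_mask()]; errors if the erosion empties the mask (reduce
#'   the radius in that case).
#' @export
shrink_mask <- function(mask, radius) {
  m <- as_pixels(mask)
  if (sum(m) == 0) stop("mask is empty", call. = FALSE)
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  out <- mask_erode(m, radius)
  if (sum(out) == 0)
    stop("erosion emptied the mask (degenerate output); reduce the radius",
         call. = FALSE)
  binary_mask(out)
}

# family code for the compiled 1-D kernel sums
.family_code <- function(family)
  match(family, c("gaussian", "uniform", "triangular")) - 1L

# Kernel constant K(0)-style normalisation for product/isotropic kernels used
# by the membership map: density = const * sum / (n * h^d).
.kernel_const <- function(kernel, d) {
  switch(kernel$family,
    gaussian = if (kernel$convention == "as_printed") (2 * pi)^(-d)
               else (2 * pi)^(-d / 2),
    uniform = 1,
    triangular = 1)
}

# Raw kernel sums for n-D queries against n-D samples, isotropic/product
# kernels, computed in row chunks to bound memory.
.kernel_sums_nd <- function(Q, S, h, family, chunk = 4096L) {
  nq <- nrow(Q)
  out <- numeric(nq)
  for (start in seq(1L, nq, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nq)
    if (family == "gaussian") {
      d2 <- matrix(0, length(idx), nrow(S))
      for (j in seq_len(ncol(Q)))
        d2 <- d2 + outer(Q[idx, j], S[, j], "-")^2
      out[idx] <- rowSums(exp(-0.5 * d2 / h^2))
    } else {
      w <- matrix(1, length(idx), nrow(S))
      for (j in seq_len(ncol(Q))) {
        u <- abs(outer(Q[idx, j], S[, j], "-")) / h
        w <- w * (if (family == "uniform") (u <= 0.5) else pmax(0, 1 - u))
      }
      out[idx] <- rowSums(w)
    }
  }
  out
}

# Per-class Parzen densities for every pixel of a normalised slice.
.class_density <- function(feats_all, samples, h, kernel) {
  d <- ncol(feats_all)
  sums <- if (d == 1L)
    kernel_sums_1d(feats_all[, 1L], samples[, 1L], h, .family_code(kernel$family))
  else
    .kernel_sums_nd(feats_all, samples, h, kernel$family)
  .kernel_const(kernel, d) * sums / (nrow(samples) * h^d)
}

.pixel_features <- function(px, config) {
  if (config$feature_mode == "intensity") {
    matrix(as.vector(px), ncol = 1L)
  } else {
    s <- if (is.null(config$spatial_scale)) 1 / max(dim(px)) else config$spatial_scale
    r <- matrix(seq_len(nrow(px)), nrow(px), ncol(px))
    cc <- matrix(seq_len(ncol(px)), nrow(px), ncol(px), byrow = TRUE)
    cbind(as.vector(px), as.vector(r) * s, as.vector(cc) * s)
  }
}

#' Estimate a per-pixel lung-membership map
#'
#' Foreground samples are the intensities inside the seed mask. A guard band
#' of width `2 * shrink_radius` around the seed is excluded from both classes
#' (near-boundary pixels have uncertain class). The background model is the
#' equal-weight average of two stratum densities: a near band (the annulus of
#' width `shrink_radius` (minimum 2 px) immediately outside the guard band,
#' i.e. the tissue the region abuts) and the far field (everything beyond). Equal
#' stratum weights keep the tissue surrounding the lung well represented even
#' when distant background (air outside the body) dominates by area, which
#' makes the posterior robust to coarse masks that overshoot the lung wall.
#' Each stratum is capped at half of `sample_cap` by seeded subsampling (the
#' full cap when the other stratum is empty).
#'
#' The membership probability of each pixel is \eqn{p = f / (f + b)} with `f`
#' and `b` the class-conditional Parzen densities at the pixel's feature
#' vector; where both densities are 0 (possible with compact-support kernels)
#' `p = 0.5`. Kernel normalisation constants cancel in the ratio, so the
#' printed and standard Gaussian conventions give identical maps.
#'
#' @param slice a [ct_slice()] with intensities already normalised to
#'   `[0, 1]` (the pipeline guarantees this; see [normalize_intensity()]).
#' @param seed_mask a nonempty [binary_mask()] seeding the foreground class.
#' @param config a [parzen_config()].
#' @return a [probability_map()].
#' @export
estimate_membership_map <- function(slice, seed_mask, config = parzen_config()) {
  px <- as_pixels(slice)
  check_same_shape(slice, seed_mask)
  if (min(px) < -1e-9 || max(px) > 1 + 1e-9)
    stop("slice must be normalised to [0, 1] before membership estimation",
         call. = FALSE)
  seed <- as_pixels(seed_mask)
  if (sum(seed) == 0) stop("seed mask is empty", call. = FALSE)

  band <- max(2L * config$shrink_radius, 1L)
  guard <- mask_dilate(seed, band)
  outer <- mask_dilate(seed, band + max(config$shrink_radius, 2L))
  near_idx <- which(outer == 1L & guard == 0L)
  far_idx <- which(outer == 0L)
  if (length(near_idx) + length(far_idx) == 0)
    stop("background band is empty: the seed (plus guard band) fills the image",
         call. = FALSE)

  feats <- .pixel_features(px, config)
  fg_idx <- which(seed == 1L)
  cap <- config$sample_cap
  cap_stratum <- function(idx, cap_i)
    if (length(idx) > cap_i) sample(idx, cap_i) else idx
  local_seed(config$seed, {
    fg_idx <- cap_stratum(fg_idx, cap)
    near_idx <- cap_stratum(near_idx,
                            if (length(far_idx) == 0) cap else cap %/% 2L)
    far_idx <- cap_stratum(far_idx,
                           if (length(near_idx) == 0) cap else cap %/% 2L)
  })

  f <- .class_density(feats, feats[fg_idx, , drop = FALSE], config$h,
                      config$kernel)
  strata <- Filter(function(ix) length(ix) > 0, list(near_idx, far_idx))
  b <- Reduce(`+`, lapply(strata, function(ix)
    .class_density(feats, feats[ix, , drop = FALSE], config$h,
                   config$kernel))) / length(strata)
  p <- ifelse(f + b > 0, f / (f + b), 0.5)
  p <- pmin(pmax(p, 0), 1)
  dim(p) <- dim(px)
  probability_map(p)
}

#' Refine a coarse lung mask by Parzen-window boundary movement
#'
#' The coarse mask (e.g. a detector's output) is eroded by `shrink_radius`
#' into a seed; the seed's interior intensities define the foreground Parzen
#' model and a guard band separates it from the background samples
#' ([estimate_membership_map()]). Starting from the coarse mask, each pass
#' adds frontier pixels (8-connected to the region) whose membership
#' probability is at least `tau` and removes region-boundary pixels whose
#' probability is below `tau`. The movement stops when at most
#' `stability_tolerance` pixels change in a pass (the boundary has lost its
#' "speed") or after `max_iterations` passes. Finally only connected
#' components that intersect the seed are kept and, if configured, interior
#' holes (vessels) are filled.
#'
#' Slices whose intensity range exceeds `[0, 1]` are min-max normalised
#' internally.
#'
#' @param slice a [ct_slice()].
#' @param coarse_mask a nonempty [binary_mask()] matching the slice shape.
#' @param config a [parzen_config()].
#' @return an object of class `segmentation_result`: a list with `mask`
#'   (refined [binary_mask()]), `probability` ([probability_map()]),
#'   `iterations_run`, `changed_per_iteration` and `converged`.
#' @export
refine_boundary <- function(slice, coarse_mask, config = parzen_config()) {
  px <- as_pixels(slice)
  check_same_shape(slice, coarse_mask)
  coarse <- as_pixels(coarse_mask)
  if (sum(coarse) == 0) stop("coarse mask is empty", call. = FALSE)
  if (min(px) < 0 || max(px) > 1)
    px <- as_pixels(normalize_intensity(ct_slice(px), "minmax"))

  seed_bm <- shrink_mask(binary_mask(coarse), config$shrink_radius)
  seed <- as_pixels(seed_bm)
  pmap <- estimate_membership_map(ct_slice(px), seed_bm, config)
  P <- pmap$values

  region <- coarse
  changed <- integer(0)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(config$max_iterations)) {
    iterations <- it
    if (config$reestimate && it > 1L && sum(region) > 0) {
      pmap <- estimate_membership_map(ct_slice(px), binary_mask(region), config)
      P <- pmap$values
    }
    nb <- has_neighbor8(region)
    add <- (region == 0L) & nb & (P >= config$tau)
    remove <- mask_boundary(region) & (P < config$tau)
    n_changed <- sum(add) + sum(remove)
    region[add] <- 1L
    region[remove] <- 0L
    changed <- c(changed, n_changed)
    if (n_changed <= config$stability_tolerance) {
      converged <- TRUE
      break
    }
  }

  if (sum(region) > 0) {
    lbl <- EBImage::bwlabel(region)
    keep <- setdiff(unique(lbl[seed == 1L]), 0)
    region <- matrix(as.integer(lbl %in% keep), nrow(region), ncol(region))
    if (config$fill_holes && sum(region) > 0)
      region <- matrix(as.integer(EBImage::fillHull(region) > 0),
                       nrow(region), ncol(region))
  }

  structure(list(mask = binary_mask(region), probability = pmap,
                 iterations_run = iterations, changed_per_iteration = changed,
                 converged = converged),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(paste0("<segmentation_result> %d x %d, %d foreground px, ",
                     "%d iteration(s), converged=%s\n"),
              x$mask$height, x$mask$width, sum(x$mask$values),
              x$iterations_run, x$converged))
  invisible(x)
}

#' Extract the lung region from a slice
#'
#' Keeps pixel values where the mask is 1 and zeroes everything else,
#' producing the masked lung image that downstream analysis (airways,
#' density) consumes.
#'
#' @param slice a [ct_slice()].
#' @param mask a [binary_mask()] of the same shape.
#' @return a [ct_slice()].
#' @export
extract_lung_region <- function(slice, mask) {
  check_same_shape(slice, mask)
  px <- as_pixels(slice) * as_pixels(mask)
  out <- slice
  if (inherits(slice, "ct_slice")) {
    out$pixels <- px
    out
  } else ct_slice(px)
}
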