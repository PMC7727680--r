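test_that("the Gaussian structuring element evaluates both conventions exactly", {
  # zero displacement: the exponent vanishes, leaving the constant
  expect_equal(gaussian_kernel(c(0, 0), diag(2), "as_printed"), 1 / (4 * pi^2))
  expect_equal(gaussian_kernel(c(0, 0), diag(2), "standard"), 1 / (2 * pi))

  # 1-D, C = [1], u = 1: (1/2pi) * exp(-1/2) under the printed form
  expect_equal(gaussian_kernel(1, matrix(1), "as_printed"),
               exp(-0.5) / (2 * pi))
  expect_equal(gaussian_kernel(1, matrix(1), "standard"), dnorm(1))

  # symmetry u <-> -u and strict decay in the Mahalanobis norm
  set.seed(11)
  C <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3)
  for (i in 1:10) {
    u <- rnorm(3)
    expect_equal(gaussian_kernel(u, C), gaussian_kernel(-u, C))
    expect_gt(gaussian_kernel(u, C), gaussian_kernel(2 * u, C))
  }

  notpd <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(gaussian_kernel(c(0, 0), notpd), "positive-definite")
})

test_that("Parzen densities follow the averaged-kernel definition", {
  uni <- kernel_spec("uniform")

  # single coincident sample, h = 1: density 1
  expect_equal(parzen_density(0.3, 0.3, h = 1, kernel = uni), 1)

  # samples {0, 2}, query 0: only the first sample is in support -> 1/2
  expect_equal(parzen_density(0, c(0, 2), h = 1, kernel = uni), 0.5)

  # duplication and permutation invariance (all kernel families)
  set.seed(21)
  for (fam in c("gaussian", "uniform", "triangular")) {
    ks <- kernel_spec(fam)
    s <- runif(7)
    z <- runif(1)
    d0 <- parzen_density(z, s, h = 0.2, kernel = ks)
    expect_equal(parzen_density(z, c(s, s), h = 0.2, kernel = ks), d0)
    expect_equal(parzen_density(z, sample(s), h = 0.2, kernel = ks), d0)
    expect_gte(d0, 0)
  }

  # term-by-term summation oracle, gaussian 1-D
  s <- c(0.1, 0.4, 0.9); z <- 0.35; h <- 0.1
  oracle <- mean(exp(-0.5 * ((z - s) / h)^2) / (2 * pi)) / h
  expect_equal(parzen_density(z, s, h = h), oracle)

  expect_error(parzen_density(0, numeric(0)), "empty")
  expect_error(parzen_density(0, 1, h = 0), "positive")
})

test_that("the Gaussian mixture density honours both normalisation conventions", {
  # single centre at the query: exponent zero, value = constant
  h <- 0.07
  expect_equal(gaussian_mixture_density(0.5, 0.5, h, "as_printed"),
               1 / (2 * pi * h))
  expect_equal(gaussian_mixture_density(0.5, 0.5, h, "standard"),
               1 / sqrt(2 * pi * h^2))

  # duplicated centres equal the single-centre value
  expect_equal(gaussian_mixture_density(0.5, rep(0.5, 10), h), 1 / (2 * pi * h))

  # the standard 1-D estimate integrates to 1 (trapezoid oracle)
  set.seed(31)
  centers <- runif(6)
  grid <- seq(min(centers) - 8 * h, max(centers) + 8 * h, length.out = 4001)
  dens <- vapply(grid, function(z)
    gaussian_mixture_density(z, centers, h, "standard"), numeric(1))
  integral <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
  expect_lt(abs(integral - 1), 0.01)

  # 1-D agreement with the generic Parzen estimate, per convention
  for (conv in c("as_printed", "standard")) {
    ks <- kernel_spec("gaussian", convention = conv)
    expect_equal(gaussian_mixture_density(0.4, centers, h, conv),
                 parzen_density(0.4, centers, h = h, kernel = ks))
  }

  expect_error(gaussian_mixture_density(0, 1, h = -1), "positive")
})

test_that("mask shrinking is disc erosion with its documented edge cases", {
  sq <- matrix(0L, 15, 15); sq[3:13, 3:13] <- 1L
  m <- binary_mask(sq)

  expect_identical(shrink_mask(m, 0)$values, sq)

  shr <- shrink_mask(m, 2)
  expected <- matrix(0L, 15, 15); expected[5:11, 5:11] <- 1L
  expect_identical(shr$values, expected)           # 11x11 square -> 7x7
  expect_identical(shr$values, bf_erode(sq, 2))    # brute-force oracle
  expect_true(all(shr$values <= sq))

  disc <- matrix(0L, 11, 11)
  for (r in 1:11) for (cc in 1:11)
    if ((r - 6)^2 + (cc - 6)^2 <= 4) disc[r, cc] <- 1L
  expect_error(shrink_mask(binary_mask(disc), 3), "degenerate")
  expect_error(shrink_mask(binary_mask(matrix(0L, 4, 4)), 1), "empty")
})

test_that("membership maps separate the two intensity classes of a phantom", {
  spec <- tiny_spec(seed = 41, sigma_noise = 0, n_vessels = 0)
  ph <- generate_phantom(spec)
  norm <- normalize_intensity(ph$slice, "minmax")
  seed_mask <- shrink_mask(ph$mask, 3)
  cfg <- parzen_config(seed = 1)
  p <- estimate_membership_map(norm, seed_mask, cfg)

  expect_true(all(p$values >= 0 & p$values <= 1))
  lung <- ph$mask$values == 1L
  body <- ph$slice$pixels == spec$mu_body
  expect_true(all(p$values[lung] > 0.5))
  expect_true(all(p$values[body] < 0.5))
})

test_that("swapping foreground and background sample sets complements the map", {
  # 10x10 two-level image. With shrink_radius 3 the guard band is 6 px and
  # the near-stratum limit 9 px, so seeding cols 1-2 makes cols 9-10 the
  # whole background sample set (far field empty) and vice versa: the two
  # runs use exactly swapped sample sets, hence exact p -> 1 - p symmetry.
  img <- matrix(0.9, 10, 10); img[, 1:2] <- 0.2
  img[3, 2] <- 0.25; img[7, 9] <- 0.85  # break constancy a little
  sl <- ct_slice(img)
  left <- matrix(0L, 10, 10); left[, 1:2] <- 1L
  right <- matrix(0L, 10, 10); right[, 9:10] <- 1L
  cfg <- parzen_config(shrink_radius = 3L, seed = 5)
  p1 <- estimate_membership_map(sl, binary_mask(left), cfg)
  p2 <- estimate_membership_map(sl, binary_mask(right), cfg)
  expect_equal(p2$values, 1 - p1$values, tolerance = 1e-12)
})

test_that("a coincident foreground sample with no background in support gives p = 1", {
  img <- matrix(0.9, 8, 8); img[, 1:3] <- 0.2
  sl <- ct_slice(img)
  seed_m <- matrix(0L, 8, 8); seed_m[, 1:2] <- 1L
  cfg <- parzen_config(h = 0.05, kernel = kernel_spec("uniform"),
                       shrink_radius = 1L, seed = 2)
  p <- estimate_membership_map(sl, binary_mask(seed_m), cfg)
  expect_equal(unname(p$values[4, 1]), 1)
  expect_error(estimate_membership_map(sl, binary_mask(matrix(1L, 8, 8)), cfg),
               "band is empty")
})

test_that("membership estimation rejects unnormalised slices and empty seeds", {
  ph <- generate_phantom(tiny_spec(seed = 51))
  expect_error(estimate_membership_map(ph$slice, ph$mask, parzen_config()),
               "normalised")
  norm <- normalize_intensity(ph$slice, "minmax")
  expect_error(estimate_membership_map(norm,
                                       binary_mask(matrix(0L, 96, 96)),
                                       parzen_config()),
               "empty")
})

test_that("refining an exact mask on a noiseless phantom is a near fixed point", {
  spec <- tiny_spec(seed = 61, sigma_noise = 0, n_vessels = 0)
  ph <- generate_phantom(spec)
  res <- refine_boundary(ph$slice, ph$mask, parzen_config(seed = 3))
  npix <- prod(dim(ph$mask))
  expect_lte(res$changed_per_iteration[1], 0.001 * npix)
  expect_gte(segmentation_metrics(res$mask, ph$mask)$dice, 0.99)
  expect_true(res$converged)
})

test_that("refinement repairs eroded, dilated and shifted coarse masks", {
  improved <- 0L
  for (seed in 1:6) {
    mode <- c("erode", "dilate", "shift")[(seed - 1) %% 3 + 1]
    ph <- generate_phantom(tiny_spec(seed = 200 + seed))
    coarse <- corrupt_mask(ph$mask, corruption_spec(mode, 3 + (seed %% 3)))
    res <- refine_boundary(ph$slice, coarse, parzen_config(seed = seed))
    expect_true(res$converged)
    expect_lte(res$iterations_run, parzen_config()$max_iterations)
    d_ref <- segmentation_metrics(res$mask, ph$mask)$dice
    d_coarse <- segmentation_metrics(coarse, ph$mask)$dice
    expect_gte(d_ref, 0.95)
    if (d_ref > d_coarse) improved <- improved + 1L
  }
  expect_gte(improved, 5L)
})

test_that("printed and standard kernel conventions give identical refinements", {
  ph <- generate_phantom(tiny_spec(seed = 71))
  coarse <- corrupt_mask(ph$mask, corruption_spec("erode", 4))
  r1 <- refine_boundary(ph$slice, coarse,
                        parzen_config(kernel = kernel_spec("gaussian",
                                                           "as_printed"),
                                      seed = 1))
  r2 <- refine_boundary(ph$slice, coarse,
                        parzen_config(kernel = kernel_spec("gaussian",
                                                           "standard"),
                                      seed = 1))
  expect_identical(r1$mask$values, r2$mask$values)
  expect_identical(r1$changed_per_iteration, r2$changed_per_iteration)
})

test_that("re-running refinement on its own output changes almost nothing", {
  ph <- generate_phantom(tiny_spec(seed = 81))
  coarse <- corrupt_mask(ph$mask, corruption_spec("erode", 4))
  r1 <- refine_boundary(ph$slice, coarse, parzen_config(seed = 1))
  r2 <- refine_boundary(ph$slice, r1$mask, parzen_config(seed = 1))
  npix <- prod(dim(ph$mask))
  expect_lte(r2$changed_per_iteration[1], 0.002 * npix)
  expect_gte(segmentation_metrics(r2$mask, r1$mask)$dice, 0.99)
})

test_that("degenerate refinement inputs raise informative errors", {
  ph <- generate_phantom(tiny_spec(seed = 91))
  expect_error(refine_boundary(ph$slice,
                               binary_mask(matrix(0L, 96, 96))),
               "empty")
  small <- binary_mask({m <- matrix(0L, 96, 96); m[48, 48] <- 1L; m})
  expect_error(refine_boundary(ph$slice, small, parzen_config(shrink_radius = 3L)),
               "degenerate")
  expect_error(refine_boundary(ph$slice, binary_mask(matrix(1L, 10, 10))),
               "shape")
})

test_that("lung extraction masks the slice exactly", {
  ph <- generate_phantom(tiny_spec(seed = 101))
  ext <- extract_lung_region(ph$slice, ph$mask)
  expect_equal(sum(ext$pixels), sum(ph$slice$pixels[ph$mask$values == 1L]))
  all1 <- binary_mask(matrix(1L, 96, 96))
  expect_identical(extract_lung_region(ph$slice, all1)$pixels, ph$slice$pixels)
  all0 <- binary_mask(matrix(0L, 96, 96))
  expect_true(all(extract_lung_region(ph$slice, all0)$pixels == 0))
})
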