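test_that("circular RMS error quotients piston and small wrapped noise correctly", {
  set.seed(1)
  th <- runif(400, -pi, pi)
  expect_equal(circular_rms_phase_error(th, th), 0)
  expect_lt(circular_rms_phase_error(th + pi / 4, th), 1e-12)
  eps <- 0.05
  noise <- runif(400, -eps, eps)
  # uniform(+-eps) noise has RMS eps/sqrt(3)
  expect_equal(circular_rms_phase_error(th + noise, th), eps / sqrt(3),
               tolerance = 0.15)
  expect_error(circular_rms_phase_error(1:3, 1:4), "support mismatch")
})

test_that("input-aberration separation subtracts the two output maps", {
  out <- expand.grid(p = -3:3, q = -3:3)
  set.seed(2)
  th <- rnorm(nrow(out))
  expect_equal(separate_input(th, th, out), rep(0, nrow(out)))
  phi <- rnorm(nrow(out))
  est <- separate_input(th, th + phi, out)
  o <- which(out$p == 0 & out$q == 0)
  expect_equal(est, phi - phi[o], tolerance = 1e-12)
  expect_error(separate_input(th, th[-1], out), "support mismatch")
})

test_that("PSF of a clean or tilted pupil has unit Strehl; aberrated less", {
  g <- make_grid(4, 64, 0.785)
  pup <- make_ideal_pupil(g, 1.0)
  psf0 <- compute_psf(NULL, pup)
  expect_equal(psf0$strehl, 1, tolerance = 1e-12)
  expect_equal(psf0$peak_loc, c(33, 33), tolerance = 1e-6)
  # integer-lattice tilt translates the peak without Strehl loss
  pq <- expand.grid(p = -32:31, q = -32:31)
  tilt <- matrix(2 * pi * 3 * pq$p / 64, 64, 64)
  psft <- compute_psf(tilt, pup)
  expect_equal(psft$strehl, 1, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(psft$peak_loc, psf0$peak_loc)))
  # moderate random aberration: peak matches the direct-sum oracle
  set.seed(3)
  ab <- matrix(rnorm(64^2, sd = 0.5), 64, 64)
  psfa <- compute_psf(ab, pup)
  oracle <- Mod(sum(exp(1i * ab[pup$support])))^2 / 64^2
  expect_equal(psfa$intensity[33, 33], oracle, tolerance = 1e-9)
  expect_lt(psfa$strehl, 1)
  expect_lte(psfa$strehl, 1 + 1e-9)
})

test_that("FWHM matches closed forms for Gaussian and Airy profiles", {
  g <- make_grid(8, 128, 0.785)
  xy <- (seq_len(128) - 65) * g$dx
  sigma <- 0.4
  gauss <- exp(-outer(xy^2, xy^2, "+") / (2 * sigma^2))
  expect_equal(fwhm(psf_profile(gauss, g)), 2 * sigma * sqrt(2 * log(2)),
               tolerance = g$dx / (2 * sigma * sqrt(2 * log(2))))
  # Airy pattern of a circular aperture: FWHM ~ 0.514 lambda / NA
  na <- 1.0
  psf <- compute_psf(NULL, make_ideal_pupil(g, na))
  expect_equal(fwhm(psf), 0.514 * g$wavelength / na, tolerance = 0.02)
  expect_error(fwhm(psf_profile(matrix(1, 128, 128), g)), "never crossed")
})

test_that("Airy fit is exact on itself and detects a Gaussian", {
  g <- make_grid(8, 128, 0.785)
  xy <- (seq_len(128) - 65) * g$dx
  r <- sqrt(outer(xy^2, xy^2, "+"))
  rate <- 1.0 * 2 * pi / 0.785
  airy <- function(x) ifelse(x < 1e-12, 1, (2 * besselJ(pmax(x, 1e-12), 1) /
                                              pmax(x, 1e-12))^2)
  f <- airy_fit(psf_profile(3.7 * airy(r * rate), g))
  expect_true(f$converged)
  expect_lt(f$residual_sq_norm, 1e-10)
  expect_equal(f$rate, rate, tolerance = 1e-6)
  expect_equal(f$scale, 3.7, tolerance = 1e-6)
  gauss <- exp(-r^2 / (2 * 0.3^2))
  fg <- airy_fit(psf_profile(gauss, g))
  expect_gt(fg$residual_sq_norm, 1e-4)
})

test_that("siemens resolution reads the sampling floor on a perfect star and the band limit on a filtered one", {
  g <- make_grid(12.8, 128, 0.785)
  star <- make_siemens_star(g, 36, 5)
  img <- Mod(star$transmittance)^2
  p_perfect <- siemens_resolution(img, g, 36, 5)
  expect_false(is.na(p_perfect))
  expect_lt(p_perfect, 3.2 * g$dx)    # resolves down to the pixel floor
  # field low-passed at the synthetic-aperture cutoff K: period -> 2*pi/K.
  # The intensity of a K-band-limited field has content out to 2K, so it is
  # rendered on a 4x oversampled grid before the contrast sweep.
  K_units <- 39   # lattice units
  idx <- seq.int(-64, 63)
  P <- matrix(idx, 128, 128); Q <- matrix(idx, 128, 128, byrow = TRUE)
  spec <- fft_forward(star$transmittance)
  spec[P^2 + Q^2 > K_units^2] <- 0
  big <- matrix(0 + 0i, 512, 512)
  big[193:320, 193:320] <- spec
  img_lp <- Mod(fft_inverse(big) * 4)^2
  g4 <- make_grid(12.8, 512, 0.785)
  p_lp <- siemens_resolution(img_lp, g4, 36, 5)
  K <- K_units * g$dk
  one_bin <- 2 * pi / (K - g$dk) - 2 * pi / K
  expect_lt(abs(p_lp - 2 * pi / K), one_bin)
  # a fixed low threshold reads into the filter tail: finer, never coarser
  p_01 <- siemens_resolution(img_lp, g4, 36, 5, contrast_threshold = 0.1)
  expect_lte(p_01, p_lp)
  expect_true(is.na(siemens_resolution(matrix(0, 128, 128), g, 36, 5)))
  expect_error(siemens_resolution(img, g, 36, 5, contrast_threshold = 1.5),
               "contrast_threshold")
})

test_that("diffraction limit follows lambda / (NA_ill + NA_col)", {
  expect_equal(round(diffraction_limit(785, 1.2, 1.2)), 327)
  expect_equal(diffraction_limit(0.633, 0.8, 0.8), 0.633 / 1.6)
  expect_equal(diffraction_limit(1000, 0.5, 0.5), 1000)
  expect_error(diffraction_limit(-1, 1, 1), "positive")
})
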