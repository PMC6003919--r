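# Shared simulation scenarios, built once per test run and cached.

# Small scene for unit tests: 4 um field, 32 px, NA 1.0 pupils.
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- make_grid(4, 32, 0.785)
      ill <- enumerate_illuminations(g, 1.0)
      pin <- make_condenser_aberration(g, 1.0, c(1, 1, 2))
      pout <- make_condenser_aberration(g, 1.0, c(0.5, 1.5, 2))
      obj <- make_siemens_star(g, 8, 1.6)
      dr <- sample_drift(ill, pi, 7)
      ds <- simulate_dataset(obj, pin, pout, dr, ill)
      cache <<- list(g = g, ill = ill, pin = pin, pout = pout, obj = obj,
                     dr = dr, ds = ds)
    }
    cache
  }
})

# Standard scenario: n = 128 grid sized so NA 1.2 (and the 2.4-NA synthetic
# aperture) fit Nyquist, 36-spoke Siemens star, radial aberrations peaking
# 6 rad at both pupil edges, drift uniform in +-pi. Solved within the
# 15-iteration budget; the conjugate-plane companion run shares phi_i/phi_o
# but has its own drift.
standard_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- make_grid(12.8, 128, 0.785)
      ill <- enumerate_illuminations(g, 1.2)
      pin <- make_condenser_aberration(g, 1.2, c(1, 2, 3))
      pout <- make_condenser_aberration(g, 1.2, c(0.5, 1.5, 4))
      obj <- make_siemens_star(g, 36, 5)
      dr <- sample_drift(ill, pi, 101)
      ds <- simulate_dataset(obj, pin, pout, dr, ill)
      fit <- run_class(ds, max_iter = 15, rel_tol = 1e-6)
      n <- g$n
      ill_lin <- lattice_index_of(ill, n)
      out_lin <- lattice_index_of(ds$out_points, n)
      cache <<- list(
        g = g, ill = ill, pin = pin, pout = pout, obj = obj, dr = dr,
        ds = ds, fit = fit, ill_lin = ill_lin, out_lin = out_lin,
        truth_i = pin$phase[ill_lin] + dr$g,
        truth_o = pout$phase[out_lin])
    }
    cache
  }
})

# Conjugate-plane companion of the standard scenario (different drift seed).
conjugate_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- standard_scenario()
      dr2 <- sample_drift(sc$ill, pi, 202)
      ds2 <- simulate_conjugate_dataset(sc$obj, sc$pin, sc$pout, dr2, sc$ill)
      fit2 <- run_class(ds2, max_iter = 15, rel_tol = 1e-6)
      cache <<- list(dr2 = dr2, ds2 = ds2, fit2 = fit2)
    }
    cache
  }
})

lattice_index_of <- function(pts, n) {
  (pts$q + n / 2) * n + (pts$p + n / 2) + 1L
}

find_image_shift <- function(ref, img, grid, max_px = 3L)
  estimate_image_shift(ref, img, grid, max_px)

# Random band-limited complex field on a grid (spectrum inside radius_units).
random_bandlimited_field <- function(grid, radius_units, seed) {
  set.seed(seed)
  n <- grid$n
  idx <- seq.int(-n / 2, n / 2 - 1)
  P <- matrix(idx, n, n); Q <- matrix(idx, n, n, byrow = TRUE)
  spec <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  spec[P^2 + Q^2 > radius_units^2] <- 0
  fft_inverse(spec)
}
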