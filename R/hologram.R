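#' Synthesize an off-axis interferogram
#'
#' Interferes a complex sample field with a tilted plane-wave reference and
#' records the camera intensity `I(r) = |E_S(r) + E_R(r)|^2`. The reference
#' is `E_R(r) = ref_amplitude * exp(-i k_R . r)`; with the package's
#' transform convention this places the spectral copy of `E_S` at `+k_R`, its
#' conjugate copy at `-k_R`, and the sample autocorrelation at the origin.
#' The carrier is specified in lattice units so later demodulation is an
#' exact index translation.
#'
#' The off-axis separation condition `|k_R| > 3 * band radius` (band radius =
#' the sample field's spectral support radius, when supplied) keeps the three
#' spectral terms disjoint; a warning is raised when it is violated.
#'
#' @param field `n x n` complex matrix: the sample field at the camera.
#' @param grid The [make_grid()] grid the field lives on.
#' @param carrier Integer lattice vector `c(p, q)` of the reference tilt.
#' @param ref_amplitude Real reference amplitude (> 0).
#' @param band_radius Optional spectral radius of `field` in rad/um, used to
#'   check the separation condition.
#' @param shot_noise_fullwell Optional full-well scaling; when given, the
#'   intensity is replaced by a Poisson draw with mean
#'   `I / max(I) * fullwell`, rescaled back (requires `seed`).
#' @param seed Seed for the optional shot noise.
#' @return An object of class `sa_interferogram`: list with `grid`,
#'   `intensity` (`n x n`, non-negative), `carrier`, `ref_amplitude`.
#' @export
synthesize_hologram <- function(field, grid, carrier, ref_amplitude,
                                band_radius = NULL,
                                shot_noise_fullwell = NULL, seed = NULL) {
  stopifnot(inherits(grid, "sa_grid"))
  field <- as.matrix(field)
  if (!all(dim(field) == grid$n)) stop("field must be n x n on the grid")
  carrier <- as.integer(round(carrier))
  if (length(carrier) != 2L) stop("carrier must be a lattice vector c(p, q)")
  n <- grid$n
  if (any(carrier < -n / 2 | carrier >= n / 2))
    stop("carrier too large for grid: lattice indices must lie in [-n/2, n/2)")
  kr_abs <- sqrt(sum(carrier^2)) * grid$dk
  if (!is.null(band_radius)) {
    if (kr_abs + band_radius > grid$k_nyquist + 1e-9)
      stop("carrier too large for grid: |k_R| + band radius exceeds Nyquist")
    if (kr_abs <= 3 * band_radius)
      warning(sprintf(paste0(
        "off-axis separation violated: |k_R| = %.4g <= 3 * band radius = %.4g",
        " rad/um; spectral terms will alias"), kr_abs, 3 * band_radius))
  }
  xy <- grid_coords(grid)
  kx <- carrier[1] * grid$dk
  ky <- carrier[2] * grid$dk
  ref <- ref_amplitude *
    exp(-1i * (outer(kx * xy, ky * xy, "+")))
  intensity <- Mod(field + ref)^2
  if (!is.null(shot_noise_fullwell)) {
    if (is.null(seed)) stop("shot noise requires a seed")
    peak <- max(intensity)
    lam <- intensity / peak * shot_noise_fullwell
    intensity <- with_seed(seed,
      matrix(stats::rpois(length(lam), as.vector(lam)), n, n)) *
      peak / shot_noise_fullwell
  }
  structure(list(grid = grid, intensity = intensity,
                 carrier = carrier, ref_amplitude = ref_amplitude),
            class = "sa_interferogram")
}

#' Demodulation settings for the 2D Hilbert transform
#'
#' Records the carrier lattice vector and the low-pass band radius and checks
#' the spectral-separation invariant: the band disk centered at `+k_R` must
#' overlap neither its mirror at `-k_R` nor the autocorrelation disk of
#' radius `2 * band_radius` at the origin.
#'
#' @param carrier Integer lattice vector `c(p, q)`.
#' @param band_radius Low-pass filter radius in rad/um (>= 0).
#' @param grid The grid the settings apply to.
#' @return An object of class `sa_demod_settings`.
#' @export
demodulation_settings <- function(carrier, band_radius, grid) {
  stopifnot(inherits(grid, "sa_grid"))
  carrier <- as.integer(round(carrier))
  if (band_radius < 0) stop("band_radius must be non-negative")
  kr_abs <- sqrt(sum(carrier^2)) * grid$dk
  # mirror-image separation: disks at +-k_R of radius b are disjoint
  margin_mirror <- 2 * kr_abs - 2 * band_radius
  # autocorrelation separation: disk at k_R vs radius-2b disk at origin
  margin_auto <- kr_abs - 3 * band_radius
  if (margin_mirror <= 0 || margin_auto <= 0)
    stop(sprintf(paste0(
      "demodulation error: spectral terms overlap (mirror margin %.4g, ",
      "autocorrelation margin %.4g rad/um); increase |k_R| or reduce the ",
      "band radius"), margin_mirror, margin_auto))
  structure(list(carrier = carrier, band_radius = band_radius, grid = grid),
            class = "sa_demod_settings")
}

#' Recover the complex field from an off-axis hologram (2D Hilbert transform)
#'
#' Fourier transforms the intensity map, crops the closed disk of
#' `band_radius` about the carrier `+k_R` with a hard edge, translates the
#' cropped spectrum by `-k_R` (an exact index shift, since carriers are
#' lattice vectors), and inverse transforms. The result equals the sample
#' field times the reference amplitude; when `ref_amplitude` is supplied
#' (directly or inside the hologram object) it is divided out.
#'
#' @param holo An [synthesize_hologram()] interferogram, or a plain `n x n`
#'   intensity matrix (then `grid` must be given via `settings$grid`).
#' @param settings A [demodulation_settings()] object.
#' @param ref_amplitude Optional override of the reference amplitude.
#' @return `n x n` complex matrix: the recovered sample field.
#' @export
hilbert_demodulate <- function(holo, settings, ref_amplitude = NULL) {
  stopifnot(inherits(settings, "sa_demod_settings"))
  if (inherits(holo, "sa_interferogram")) {
    intensity <- holo$intensity
    if (is.null(ref_amplitude)) ref_amplitude <- holo$ref_amplitude
    stop_if_grid_mismatch(holo$grid, settings$grid, "hologram and settings")
  } else {
    intensity <- as.matrix(holo)
  }
  grid <- settings$grid
  n <- grid$n
  if (!all(dim(intensity) == n)) stop("hologram must be n x n on the grid")
  spec <- fft_forward(intensity)
  pq <- lattice_pq(n)
  dist <- sqrt((pq$P - settings$carrier[1])^2 +
               (pq$Q - settings$carrier[2])^2) * grid$dk
  keep <- dist <= settings$band_radius + 1e-9 * grid$dk
  spec[!keep] <- 0 + 0i
  # exact index translation by -k_R
  shifted <- matrix(0 + 0i, n, n)
  src_p <- grid_index(n)
  dst_p <- src_p - settings$carrier[1]
  dst_q <- src_p - settings$carrier[2]
  ok_p <- dst_p >= -n / 2 & dst_p < n / 2
  ok_q <- dst_q >= -n / 2 & dst_q < n / 2
  shifted[dst_p[ok_p] + n / 2 + 1, dst_q[ok_q] + n / 2 + 1] <-
    spec[which(ok_p), which(ok_q)]
  field <- fft_inverse(shifted)
  if (!is.null(ref_amplitude)) field <- field / ref_amplitude
  field
}
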