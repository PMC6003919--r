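#' Sampling grid for field and frequency space
#'
#' Defines the shared real-space / frequency-space sampling contract used by
#' every other object in the package. A square field of view of side `fov`
#' (micrometres) sampled on `n` pixels per side induces a spatial-frequency
#' lattice with spacing `dk = 2*pi/fov` (rad/um). Lattice points are indexed by
#' integer pairs (p, q) in \code{[-n/2, n/2)}; the physical frequency of a
#' lattice point is `(p, q) * dk`. The free-space wavenumber is
#' `k0 = 2*pi/wavelength`.
#'
#' @param fov Field of view in micrometres (side of the square), > 0.
#' @param n Pixels per side; even integer >= 16.
#' @param wavelength Vacuum wavelength in micrometres, > 0.
#'
#' @return An object of class `sa_grid`: a list with elements `fov`, `n`,
#'   `wavelength`, `dk` (frequency spacing, rad/um), `k0` (rad/um),
#'   `k_nyquist` (`n/2 * dk`, rad/um) and `dx` (pixel pitch, um).
#'
#' @examples
#' g <- make_grid(fov = 50, n = 64, wavelength = 0.785)
#' g$dk    # 2*pi/50
#' g$k0    # ~8.0037 rad/um
#' @export
make_grid <- function(fov, n, wavelength) {
  if (!is.numeric(fov) || length(fov) != 1L || !is.finite(fov) || fov <= 0)
    stop("grid sizing error: 'fov' must be a positive length in micrometres")
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n != round(n))
    stop("grid sizing error: 'n' must be an integer")
  n <- as.integer(n)
  if (n < 16L || n %% 2L != 0L)
    stop("grid sizing error: 'n' must be even and >= 16")
  if (!is.numeric(wavelength) || length(wavelength) != 1L ||
      !is.finite(wavelength) || wavelength <= 0)
    stop("grid sizing error: 'wavelength' must be a positive length in micrometres")
  dk <- 2 * pi / fov
  structure(
    list(fov = fov, n = n, wavelength = wavelength,
         dk = dk, k0 = 2 * pi / wavelength,
         k_nyquist = (n / 2) * dk, dx = fov / n),
    class = "sa_grid")
}

#' @export
print.sa_grid <- function(x, ...) {
  cat(sprintf("<sa_grid> fov = %g um, n = %d, wavelength = %g um\n",
              x$fov, x$n, x$wavelength))
  cat(sprintf("  dk = %.6g rad/um, k0 = %.6g rad/um, Nyquist = %.6g rad/um\n",
              x$dk, x$k0, x$k_nyquist))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$fov, b$fov)) && a$n == b$n &&
    isTRUE(all.equal(a$wavelength, b$wavelength))
}

stop_if_grid_mismatch <- function(a, b, what = "objects") {
  if (!same_grid(a, b)) stop("grid mismatch: ", what, " live on different grids")
}

# Integer lattice index (p or q) for each array row/column, p in [-n/2, n/2).
grid_index <- function(n) seq.int(-n / 2L, n / 2L - 1L)

# Real-space pixel coordinates (um), origin at array index n/2 + 1.
grid_coords <- function(grid) grid_index(grid$n) * grid$dx

# Matrices of lattice indices P[i, j] = p_i, Q[i, j] = q_j (centered layout:
# array element [i, j] holds lattice point p = i - n/2 - 1, q = j - n/2 - 1).
lattice_pq <- function(n) {
  idx <- grid_index(n)
  list(P = matrix(idx, n, n), Q = matrix(idx, n, n, byrow = TRUE))
}

# |k| in rad/um on the centered lattice.
lattice_kabs <- function(grid) {
  pq <- lattice_pq(grid$n)
  sqrt(pq$P^2 + pq$Q^2) * grid$dk
}

# Linear index into an n x n centered array for integer lattice offsets (p, q).
lattice_linear <- function(p, q, n) {
  if (any(p < -n / 2 | p >= n / 2 | q < -n / 2 | q >= n / 2))
    stop("lattice point outside the [-n/2, n/2) index range")
  (q + n / 2) * n + (p + n / 2) + 1L
}

# Quadrant swap for even n (its own inverse), mapping array index n/2+1 <-> 1.
fftshift2 <- function(x) {
  n <- nrow(x)
  idx <- c((n / 2 + 1):n, 1:(n / 2))
  x[idx, idx, drop = FALSE]
}

#' Unitary discrete Fourier transform pair on the centered lattice
#'
#' Forward transform from real space to the centered frequency lattice and its
#' inverse. The pair is unitary (Parseval-exact: `sum(Mod(x)^2)` is preserved)
#' and uses the package-wide convention that both real space and frequency
#' space place their origin at array index `n/2 + 1`. A plane wave
#' `exp(i k . r)` with `k = (p, q) * dk` transforms to a single peak at lattice
#' point `(p, q)`.
#'
#' @param x An `n x n` (complex or real) matrix.
#' @return An `n x n` complex matrix.
#' @seealso [make_grid()] for the lattice convention.
#' @export
fft_forward <- function(x) {
  n <- nrow(x)
  fftshift2(stats::fft(fftshift2(x))) / n
}

#' @rdname fft_forward
#' @export
fft_inverse <- function(x) {
  n <- nrow(x)
  fftshift2(stats::fft(fftshift2(x), inverse = TRUE)) / n
}

# Deterministic enumeration of lattice points inside a closed disk
# |k| <= radius_units * dk, ordered row-major by (q, p): q varies slowest.
# Returns a data.frame with integer columns p, q.
disk_points <- function(n, radius_units) {
  idx <- grid_index(n)
  q <- rep(idx, each = length(idx))
  p <- rep(idx, times = length(idx))
  keep <- (p^2 + q^2) <= radius_units^2 + 1e-9
  data.frame(p = p[keep], q = q[keep])
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Wrap phase into (-pi, pi].
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
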