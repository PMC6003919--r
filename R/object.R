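#' Object fields (sample transmittance) on the shared grid
#'
#' An object field holds the complex transmittance of a thin sample over the
#' real-space pixels of a grid. Its angular spectrum is the unitary forward
#' transform of the transmittance ([object_spectrum()]); the two views are an
#' exact transform pair.
#'
#' @param grid A [make_grid()] grid.
#' @param transmittance `n x n` complex (or real) matrix of pixel
#'   transmittance values.
#' @return An object of class `sa_object`: list with `grid`, `transmittance`.
#' @export
make_object <- function(grid, transmittance) {
  stopifnot(inherits(grid, "sa_grid"))
  transmittance <- as.matrix(transmittance)
  if (!all(dim(transmittance) == grid$n))
    stop("transmittance must be an n x n matrix matching the grid")
  structure(list(grid = grid, transmittance = transmittance + 0i),
            class = "sa_object")
}

#' @export
print.sa_object <- function(x, ...) {
  cat(sprintf("<sa_object> %d x %d pixels on a %g um field\n",
              x$grid$n, x$grid$n, x$grid$fov))
  invisible(x)
}

#' Angular spectrum of an object field
#'
#' Unitary forward transform of the transmittance onto the centered frequency
#' lattice. `fft_inverse(object_spectrum(obj))` reproduces the transmittance
#' to machine precision.
#'
#' @param obj An [make_object()] object field.
#' @return `n x n` complex matrix over the centered frequency lattice.
#' @export
object_spectrum <- function(obj) {
  stopifnot(inherits(obj, "sa_object"))
  fft_forward(obj$transmittance)
}

#' Siemens-star amplitude resolution target
#'
#' Binary amplitude target of `n_spokes` alternating opaque/transparent
#' angular sectors of equal width inside radius `r_outer`, transparent
#' outside. The local azimuthal period at radius `r` is
#' `2*pi*r / (n_spokes/2)`, so resolution can be read off as the finest
#' resolved period. A pixel at polar angle `theta` (measured from the grid
#' origin) and radius `r < r_outer` is opaque iff
#' `floor(theta * n_spokes / (2*pi))` is even.
#'
#' @param grid A [make_grid()] grid.
#' @param n_spokes Even integer >= 4; total number of sectors.
#' @param r_outer Outer radius of the star in micrometres, <= fov/2.
#' @return An `sa_object` with binary (0/1) transmittance.
#' @export
make_siemens_star <- function(grid, n_spokes, r_outer) {
  stopifnot(inherits(grid, "sa_grid"))
  if (!is.numeric(n_spokes) || length(n_spokes) != 1L ||
      n_spokes != round(n_spokes) || n_spokes < 4 || n_spokes %% 2 != 0)
    stop("n_spokes must be an even integer >= 4")
  if (!is.numeric(r_outer) || length(r_outer) != 1L ||
      r_outer <= 0 || r_outer > grid$fov / 2)
    stop("r_outer must be positive and at most fov/2")
  xy <- grid_coords(grid)
  X <- matrix(xy, grid$n, grid$n)
  Y <- matrix(xy, grid$n, grid$n, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X) %% (2 * pi)
  sector <- floor(theta * n_spokes / (2 * pi))
  t <- ifelse(r < r_outer & sector %% 2 == 0, 0, 1)
  make_object(grid, t)
}

#' Smooth random phase object ("yeast-like" granular phase sample)
#'
#' Unit-amplitude phase object built from `n_blobs` randomly placed Gaussian
#' phase bumps, emulating transparent biological samples with granular
#' internal structure. The phase is rescaled so its maximum magnitude equals
#' `max_phase` (if any blob was drawn). Fully deterministic under `seed`.
#'
#' @param grid A [make_grid()] grid.
#' @param n_blobs Number of Gaussian bumps (0 gives a unit transmittance).
#' @param max_phase Maximum |phase| in radians, <= pi.
#' @param seed Integer seed.
#' @param blob_sigma Bump standard deviation in micrometres (default fov/16).
#' @return An `sa_object` with `Mod(transmittance) == 1` everywhere.
#' @export
make_phase_blobs <- function(grid, n_blobs, max_phase, seed,
                             blob_sigma = grid$fov / 16) {
  stopifnot(inherits(grid, "sa_grid"))
  if (max_phase > pi) stop("max_phase must be <= pi")
  if (n_blobs < 0 || n_blobs != round(n_blobs)) stop("n_blobs must be a non-negative integer")
  phase <- matrix(0, grid$n, grid$n)
  if (n_blobs > 0) {
    xy <- grid_coords(grid)
    X <- matrix(xy, grid$n, grid$n)
    Y <- matrix(xy, grid$n, grid$n, byrow = TRUE)
    half <- grid$fov / 2
    with_seed(seed, {
      for (b in seq_len(n_blobs)) {
        cx <- stats::runif(1, -half * 0.7, half * 0.7)
        cy <- stats::runif(1, -half * 0.7, half * 0.7)
        amp <- stats::runif(1, 0.3, 1)
        sg <- blob_sigma * stats::runif(1, 0.5, 1.5)
        phase <- phase + amp * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2))
      }
    })
    m <- max(abs(phase))
    if (m > 0) phase <- phase * (max_phase / m)
  }
  make_object(grid, exp(1i * phase))
}

#' Point-like object (single bright pixel on a dark field)
#'
#' A delta-function target at the grid origin: the object spectrum is flat,
#' which makes correlation-based aberration estimates exact in closed form.
#' An optional uniform background emulates a partially transparent mount.
#'
#' @param grid A [make_grid()] grid.
#' @param amplitude Pixel amplitude at the origin.
#' @param background Uniform background transmittance (default 0).
#' @return An `sa_object`.
#' @export
make_point_object <- function(grid, amplitude = 1, background = 0) {
  stopifnot(inherits(grid, "sa_grid"))
  t <- matrix(background + 0i, grid$n, grid$n)
  c0 <- grid$n / 2 + 1
  t[c0, c0] <- amplitude
  make_object(grid, t)
}
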