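#' Enumerate illumination wavevectors covering the input aperture
#'
#' Lists every frequency-lattice point inside the closed illumination cutoff
#' `|k| <= na_ill * k0`. These are the orthogonal free modes of the field of
#' view within the aperture: one plane-wave illumination per lattice point.
#' The order is deterministic, row-major by (q, p): q varies slowest.
#'
#' @param grid A [make_grid()] grid.
#' @param na_ill Illumination numerical aperture; `na_ill * k0` must not
#'   exceed the grid Nyquist frequency.
#' @return An object of class `sa_illuminations`: a data.frame with integer
#'   lattice columns `p`, `q` and physical columns `kx`, `ky` (rad/um), with
#'   attributes `grid` and `na_ill`.
#' @examples
#' g <- make_grid(12.8, 128, 0.785)
#' ill <- enumerate_illuminations(g, 1.2)
#' nrow(ill)  # number of plane-wave illuminations
#' @export
enumerate_illuminations <- function(grid, na_ill) {
  stopifnot(inherits(grid, "sa_grid"))
  if (!is.numeric(na_ill) || length(na_ill) != 1L || na_ill <= 0)
    stop("illumination sizing error: 'na_ill' must be positive")
  kcut <- na_ill * grid$k0
  if (kcut > grid$k_nyquist + 1e-9)
    stop(sprintf(paste0(
      "illumination sizing error: na_ill * k0 = %.4g rad/um exceeds the grid ",
      "Nyquist frequency %.4g rad/um"), kcut, grid$k_nyquist))
  pts <- disk_points(grid$n, kcut / grid$dk)
  pts$kx <- pts$p * grid$dk
  pts$ky <- pts$q * grid$dk
  structure(pts, grid = grid, na_ill = na_ill,
            class = c("sa_illuminations", "data.frame"))
}

# Output-side detection lattice: all points within the collection aperture,
# same deterministic order as the illumination enumeration.
output_support_points <- function(grid, na_col) {
  out <- enumerate_illuminations(grid, na_col)
  attr(out, "na_ill") <- NULL
  attr(out, "na_col") <- na_col
  class(out) <- "data.frame"
  out
}

#' Per-illumination uncontrolled phase drift
#'
#' Draws one global phase per illumination, independent and uniform in
#' `[-magnitude, magnitude]`, emulating optical-path-length fluctuation
#' between the sample and reference arms over a scanned acquisition. The
#' draw is fully determined by `seed`.
#'
#' @param illums An [enumerate_illuminations()] set.
#' @param magnitude Half-width of the uniform distribution in radians,
#'   `0 <= magnitude <= pi`.
#' @param seed Integer seed.
#' @return An object of class `sa_drift`: list with `g` (radians, one per
#'   illumination, in illumination order), `magnitude`, `seed`.
#' @export
sample_drift <- function(illums, magnitude, seed) {
  stopifnot(inherits(illums, "sa_illuminations"))
  if (magnitude < 0 || magnitude > pi)
    stop("drift magnitude must be in [0, pi]")
  g <- with_seed(seed, stats::runif(nrow(illums), -magnitude, magnitude))
  structure(list(g = g, magnitude = magnitude, seed = seed),
            class = "sa_drift")
}
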