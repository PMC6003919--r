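#' Ideal pupil function with a hard numerical-aperture cutoff
#'
#' A pupil is the complex transfer function of a lens over transverse
#' wavevectors: unit amplitude on the closed disk `|k| <= na * k0`, zero
#' outside, with a phase map (the aberration) defined only on the support.
#' `make_ideal_pupil` builds the aberration-free pupil (phase identically 0).
#'
#' @param grid A [make_grid()] grid.
#' @param na Numerical aperture (dimensionless, > 0). The cutoff `na * k0`
#'   must not exceed the grid Nyquist frequency `n/2 * dk`.
#'
#' @return An object of class `sa_pupil`: list with `grid`, `na`, `support`
#'   (`n x n` logical, centered layout), `phase` (`n x n` numeric, radians;
#'   meaningful only where `support` is `TRUE`).
#' @examples
#' g <- make_grid(12.8, 128, 0.785)
#' p <- make_ideal_pupil(g, 1.2)
#' sum(p$support)  # lattice points inside the 1.2-NA cutoff
#' @export
make_ideal_pupil <- function(grid, na) {
  stopifnot(inherits(grid, "sa_grid"))
  if (!is.numeric(na) || length(na) != 1L || !is.finite(na) || na <= 0)
    stop("pupil sizing error: 'na' must be a positive number")
  kcut <- na * grid$k0
  if (kcut > grid$k_nyquist + 1e-9)
    stop(sprintf(paste0(
      "pupil sizing error: na * k0 = %.4g rad/um exceeds the grid Nyquist ",
      "frequency %.4g rad/um; increase n or reduce fov/na"),
      kcut, grid$k_nyquist))
  support <- lattice_kabs(grid) <= kcut + 1e-9 * grid$dk
  structure(
    list(grid = grid, na = na, support = support,
         phase = matrix(0, grid$n, grid$n)),
    class = "sa_pupil")
}

#' @export
print.sa_pupil <- function(x, ...) {
  cat(sprintf("<sa_pupil> na = %g, %d lattice points on support\n",
              x$na, sum(x$support)))
  if (any(x$phase[x$support] != 0))
    cat(sprintf("  phase range on support: [%.3g, %.3g] rad\n",
                min(x$phase[x$support]), max(x$phase[x$support])))
  invisible(x)
}

# Complex pupil values P^a = exp(i * phase) on support, 0 off support.
pupil_values <- function(pupil) {
  v <- matrix(0 + 0i, pupil$grid$n, pupil$grid$n)
  v[pupil$support] <- exp(1i * pupil$phase[pupil$support])
  v
}

#' Condenser-like pupil aberration
#'
#' Builds an aberrated pupil whose phase is an even-power radial polynomial in
#' the normalized pupil radius `rho = |k| / (na * k0)`, optionally contaminated
#' by low-order asymmetric terms. The radial part is
#' `phase(k) = sum_j radial_coeffs[j] * rho^(2*j + 2)` (powers 2, 4, 6, ...),
#' which is zero at the pupil center (piston-free) and reproduces the steep,
#' spherically symmetric phase ramps characteristic of high-NA condenser
#' lenses used as objectives: by putting weight on the higher even powers the
#' aberration stays mild below ~0.8 NA and grows steeply toward the edge.
#'
#' @param grid A [make_grid()] grid.
#' @param na Numerical aperture of the pupil.
#' @param radial_coeffs Numeric vector `c_1, c_2, ...`; coefficient `c_j`
#'   multiplies `rho^(2*j)`. The phase at the pupil edge (`rho = 1`) equals
#'   `sum(radial_coeffs)`. Default `numeric(0)` (no radial aberration).
#' @param asym_coeffs Optional named numeric vector of low-order asymmetric
#'   terms (radians at the pupil edge): any of `astig_x` (`rho^2 cos(2 phi)`),
#'   `astig_y` (`rho^2 sin(2 phi)`), `coma_x` (`rho^3 cos(phi)`),
#'   `coma_y` (`rho^3 sin(phi)`).
#'
#' @return An `sa_pupil` whose `phase` carries the aberration.
#' @examples
#' g <- make_grid(12.8, 128, 0.785)
#' ab <- make_condenser_aberration(g, 1.2, radial_coeffs = c(1, 2, 3))
#' max(ab$phase[ab$support])  # 6 rad at the pupil edge
#' @export
make_condenser_aberration <- function(grid, na, radial_coeffs = numeric(0),
                                      asym_coeffs = numeric(0)) {
  if (length(radial_coeffs) && any(!is.finite(radial_coeffs)))
    stop("radial_coeffs must be finite")
  if (length(asym_coeffs) && any(!is.finite(asym_coeffs)))
    stop("asym_coeffs must be finite")
  pupil <- make_ideal_pupil(grid, na)
  pq <- lattice_pq(grid$n)
  kabs <- sqrt(pq$P^2 + pq$Q^2) * grid$dk
  rho <- kabs / (na * grid$k0)
  phase <- matrix(0, grid$n, grid$n)
  for (j in seq_along(radial_coeffs))
    phase <- phase + radial_coeffs[j] * rho^(2 * j)
  if (length(asym_coeffs)) {
    unknown <- setdiff(names(asym_coeffs),
                       c("astig_x", "astig_y", "coma_x", "coma_y"))
    if (length(unknown) || is.null(names(asym_coeffs)))
      stop("asym_coeffs must be named: astig_x, astig_y, coma_x, coma_y")
    phi <- atan2(pq$Q, pq$P)
    get0c <- function(nm) if (nm %in% names(asym_coeffs)) asym_coeffs[[nm]] else 0
    phase <- phase +
      get0c("astig_x") * rho^2 * cos(2 * phi) +
      get0c("astig_y") * rho^2 * sin(2 * phi) +
      get0c("coma_x") * rho^3 * cos(phi) +
      get0c("coma_y") * rho^3 * sin(phi)
  }
  phase[!pupil$support] <- 0
  pupil$phase <- phase
  pupil
}
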