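#' Isolate the pure input aberration from two measurement configurations
#'
#' The output correction of a sample-plane run converges to `phi_o`; the
#' output correction of a conjugate-plane run (test target before the input
#' condenser) converges to `phi_i + phi_o` because the two pupils multiply on
#' the output side there. Their wrapped difference therefore estimates the
#' pure input aberration `phi_i`, free of the per-illumination drift that
#' contaminates the input correction. The returned map is piston-normalized
#' (zero at the lattice origin).
#'
#' @param theta_o_main Output correction of the sample-plane run (vector over
#'   `out_points`).
#' @param theta_o_conjugate Output correction of the conjugate-plane run on
#'   the same support.
#' @param out_points Output-support lattice (data.frame with `p`, `q`).
#' @return Numeric vector over `out_points`: the `phi_i` estimate, wrapped
#'   into `(-pi, pi]`.
#' @export
separate_input <- function(theta_o_main, theta_o_conjugate, out_points) {
  if (length(theta_o_main) != length(theta_o_conjugate) ||
      length(theta_o_main) != nrow(out_points))
    stop("support mismatch: the two output corrections must share the ",
         "output-pupil lattice")
  d <- wrap_phase(theta_o_conjugate - theta_o_main)
  o <- which(out_points$p == 0 & out_points$q == 0)
  if (length(o)) d <- wrap_phase(d - d[o[1]])
  d
}

#' Circular RMS error between two phase maps
#'
#' Recovery metric used throughout: wraps the pointwise difference into
#' `(-pi, pi]`, aligns away the gauge freedoms (piston by the circular mean;
#' tilt, when lattice coordinates are given, by an iterated least-squares fit
#' on the wrapped residual), and returns the root-mean-square of what
#' remains.
#'
#' @param estimate,truth Numeric phase vectors on the same support.
#' @param points Optional lattice data.frame (`p`, `q`) enabling tilt
#'   alignment; with `NULL` only piston is aligned.
#' @return RMS phase error in radians.
#' @export
circular_rms_phase_error <- function(estimate, truth, points = NULL) {
  sqrt(mean(align_phase_residual(estimate, truth, points)^2))
}

#' Gauge-aligned wrapped residual between two phase maps
#'
#' The residual [circular_rms_phase_error()] is built on: the pointwise
#' difference wrapped into `(-pi, pi]`, with the piston (circular mean) and —
#' when lattice coordinates are supplied — the tilt removed by an iterated
#' least-squares fit on the wrapped residual. Useful on its own to inspect
#' the spatial structure of a recovery error or to form the residual pupil
#' phase whose PSF quantifies the corrected system ([compute_psf()]).
#'
#' @inheritParams circular_rms_phase_error
#' @return Numeric vector of aligned, wrapped residuals (radians).
#' @export
align_phase_residual <- function(estimate, truth, points = NULL) {
  if (length(estimate) != length(truth))
    stop("support mismatch: estimate and truth differ in length")
  d <- wrap_phase(estimate - truth)
  d <- wrap_phase(d - Arg(mean(exp(1i * d))))
  if (!is.null(points)) {
    stopifnot(nrow(points) == length(d))
    X <- cbind(1, points$p, points$q)
    for (pass in 1:3) {
      beta <- qr.solve(X, d)
      d <- wrap_phase(d - X %*% beta)
    }
  }
  as.vector(d)
}

#' Point-spread function of a pupil carrying a residual phase
#'
#' Forms the coherent PSF of a unit-amplitude pupil with the given residual
#' phase: `intensity = |F^-1[ support * exp(i phase) ]|^2`. The Strehl ratio
#' is the peak intensity divided by the peak of the zero-phase pupil of
#' identical support (so a pure tilt, which merely translates the peak, has
#' Strehl 1). The peak is localized to sub-pixel precision by quadratic
#' interpolation.
#'
#' @param residual_phase `n x n` phase matrix in radians (values off the
#'   pupil support are ignored), or `NULL` for the aberration-free PSF.
#' @param pupil An `sa_pupil` providing grid and support.
#' @return An object of class `sa_psf`: list with `grid`, `intensity`
#'   (`n x n`), `peak_value`, `peak_loc` (sub-pixel array indices), `strehl`.
#' @export
compute_psf <- function(residual_phase, pupil) {
  stopifnot(inherits(pupil, "sa_pupil"))
  if (sum(pupil$support) == 0L) stop("empty pupil support")
  n <- pupil$grid$n
  P <- matrix(0 + 0i, n, n)
  if (is.null(residual_phase)) {
    P[pupil$support] <- 1
  } else {
    residual_phase <- as.matrix(residual_phase)
    if (!all(dim(residual_phase) == n))
      stop("residual_phase must be n x n on the pupil grid")
    P[pupil$support] <- exp(1i * residual_phase[pupil$support])
  }
  intensity <- Mod(fft_inverse(P))^2
  peak0 <- (sum(pupil$support) / n)^2   # zero-phase peak, all terms in phase
  peak <- max(intensity)
  loc <- which(intensity == peak, arr.ind = TRUE)[1, ]
  subpix <- function(im, i, j, axis) {
    if (axis == 1) {
      if (i <= 1 || i >= nrow(im)) return(0)
      y <- im[(i - 1):(i + 1), j]
    } else {
      if (j <= 1 || j >= ncol(im)) return(0)
      y <- im[i, (j - 1):(j + 1)]
    }
    den <- y[1] - 2 * y[2] + y[3]
    if (den == 0) 0 else 0.5 * (y[1] - y[3]) / den
  }
  peak_loc <- c(loc[1] + subpix(intensity, loc[1], loc[2], 1),
                loc[2] + subpix(intensity, loc[1], loc[2], 2))
  structure(
    list(grid = pupil$grid, intensity = intensity, peak_value = peak,
         peak_loc = unname(peak_loc), strehl = peak / peak0),
    class = "sa_psf")
}

#' Construct a PSF profile from an intensity map
#'
#' Wraps a pre-computed non-negative intensity map (e.g. an analytic test
#' pattern or a reconstructed focus) in the same container [compute_psf()]
#' returns, so that [fwhm()] and [airy_fit()] can be applied to it. Strehl is
#' not defined for a bare map and is set to `NA`.
#'
#' @param intensity `n x n` non-negative matrix.
#' @param grid The [make_grid()] grid.
#' @return An `sa_psf`.
#' @export
psf_profile <- function(intensity, grid) {
  stopifnot(inherits(grid, "sa_grid"))
  intensity <- as.matrix(intensity)
  if (!all(dim(intensity) == grid$n)) stop("intensity must be n x n")
  if (any(intensity < 0)) stop("intensity must be non-negative")
  peak <- max(intensity)
  loc <- which(intensity == peak, arr.ind = TRUE)[1, ]
  structure(
    list(grid = grid, intensity = intensity, peak_value = peak,
         peak_loc = unname(c(loc[1], loc[2])), strehl = NA_real_),
    class = "sa_psf")
}

#' @export
print.sa_psf <- function(x, ...) {
  cat(sprintf("<sa_psf> peak %.4g at (%.2f, %.2f)%s\n", x$peak_value,
              x$peak_loc[1], x$peak_loc[2],
              if (is.na(x$strehl)) "" else sprintf(", Strehl %.4f", x$strehl)))
  invisible(x)
}

# Bilinear interpolation of a matrix at fractional array indices.
interp2 <- function(im, i, j) {
  n1 <- nrow(im); n2 <- ncol(im)
  i <- pmin(pmax(i, 1), n1); j <- pmin(pmax(j, 1), n2)
  i0 <- pmin(floor(i), n1 - 1); j0 <- pmin(floor(j), n2 - 1)
  di <- i - i0; dj <- j - j0
  im[cbind(i0, j0)] * (1 - di) * (1 - dj) +
    im[cbind(i0 + 1, j0)] * di * (1 - dj) +
    im[cbind(i0, j0 + 1)] * (1 - di) * dj +
    im[cbind(i0 + 1, j0 + 1)] * di * dj
}

#' Full width at half maximum of a PSF profile
#'
#' Width at half the (sub-pixel interpolated) peak along a straight line
#' through the peak at the given angle, with linear interpolation between
#' samples. Errors if the half-maximum level is never crossed on either side
#' within the grid.
#'
#' @param profile An `sa_psf`.
#' @param angle Line direction in radians (0 = along the first array axis).
#' @return FWHM in micrometres.
#' @export
fwhm <- function(profile, angle = 0) {
  stopifnot(inherits(profile, "sa_psf"))
  grid <- profile$grid
  step <- 0.25  # pixels
  tmax <- grid$n / 2
  t <- seq(0, tmax, by = step)
  half <- interp2(profile$intensity, profile$peak_loc[1],
                  profile$peak_loc[2]) / 2
  cross <- function(dir) {
    i <- profile$peak_loc[1] + dir * t * cos(angle)
    j <- profile$peak_loc[2] + dir * t * sin(angle)
    inside <- i >= 1 & i <= grid$n & j >= 1 & j <= grid$n
    v <- interp2(profile$intensity, i[inside], j[inside])
    below <- which(v < half)
    if (!length(below) || below[1] == 1L)
      stop("half-maximum level never crossed within the grid")
    b <- below[1]
    frac <- (v[b - 1] - half) / (v[b - 1] - v[b])
    t[b - 1] + frac * step
  }
  (cross(1) + cross(-1)) * grid$dx
}

airy_intensity <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-12
  out[nz] <- (2 * besselJ(abs(x[nz]), 1) / abs(x[nz]))^2
  out
}

#' Fit an Airy-pattern model to a PSF
#'
#' Least-squares fit of `scale * [2 J1(x)/x]^2`, `x = r * rate`, to the PSF
#' pixels from the (sub-pixel) center out through the first dark ring
#' (`x <= 3.8317`), the region where the visual agreement of a focused spot
#' with the Airy model is judged. The fit domain is set from an initial rate
#' estimate and refined once. A non-convergent fit is reported in the
#' record, not raised.
#'
#' @param profile An `sa_psf`.
#' @return A list: `scale`, `rate` (rad/um; the aperture cutoff `na * k0`
#'   for a true Airy pattern), `residual_sq_norm`
#'   (`sum(residual^2) / sum(data^2)` over the fit domain), `converged`.
#' @export
airy_fit <- function(profile) {
  stopifnot(inherits(profile, "sa_psf"))
  grid <- profile$grid
  f <- fwhm(profile)                       # initial scale of the core
  rate0 <- 2 * 1.61633 / f                 # Airy half-max at x = 1.61633
  idx <- grid_index(grid$n)
  R <- sqrt(outer((idx - (profile$peak_loc[1] - grid$n / 2 - 1))^2,
                  (idx - (profile$peak_loc[2] - grid$n / 2 - 1))^2, "+")) *
    grid$dx
  fit1 <- NULL
  rate <- rate0
  for (pass in 1:2) {
    dom <- R <= 3.8317 / rate
    df <- data.frame(r = R[dom], I = profile$intensity[dom])
    fit1 <- tryCatch(
      minpack.lm::nlsLM(I ~ scale * airy_intensity(r * rate), data = df,
                        start = list(scale = max(df$I), rate = rate),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit1)) break
    rate <- abs(stats::coef(fit1)[["rate"]])
  }
  if (is.null(fit1))
    return(list(scale = NA_real_, rate = NA_real_,
                residual_sq_norm = NA_real_, converged = FALSE))
  dom <- R <= 3.8317 / rate
  data <- profile$intensity[dom]
  pred <- stats::predict(fit1, newdata = data.frame(r = R[dom]))
  list(scale = stats::coef(fit1)[["scale"]], rate = rate,
       residual_sq_norm = sum((data - pred)^2) / sum(data^2),
       converged = TRUE)
}

#' Finest resolved azimuthal period of a Siemens-star image
#'
#' Automates reading resolution off a Siemens-star image: sweeps circles of
#' decreasing radius about the star center, computes the Michelson contrast
#' of the azimuthal intensity profile at the spoke frequency
#' (`n_spokes/2` cycles per turn), and returns the local azimuthal period
#' `2*pi*r* / (n_spokes/2)` at the smallest radius `r*` of the contiguous
#' resolved zone reaching in from the star's outer edge — the sweep stops at
#' the first circle whose contrast drops below the threshold, so isolated
#' speckle passes deeper in never count as "resolved". Radii whose local
#' period falls below two pixels (the sampling floor) are excluded. Returns
#' `NA` ("unresolved") when even the outermost circles fail.
#'
#' With `contrast_threshold = NULL` (default) the threshold is
#' aperture-calibrated: half the median contrast of the outer third of the
#' sweep (the resolved plateau). An ideal aperture transmits exactly half
#' the amplitude at its cutoff frequency, so the half-plateau crossing sits
#' at the cutoff radius by construction instead of one PSF width inside the
#' filter tail; a fixed numeric threshold (e.g. 0.1) is also accepted.
#'
#' @param image `n x n` non-negative intensity map containing the star.
#' @param grid The [make_grid()] grid.
#' @param n_spokes Number of star sectors (as built).
#' @param r_outer Outer star radius in micrometres.
#' @param contrast_threshold `NULL` (half-plateau, default) or a fixed
#'   Michelson contrast threshold in (0, 1).
#' @param center Star center in micrometres, default the grid origin.
#' @return Finest resolved period in micrometres, or `NA_real_`.
#' @export
siemens_resolution <- function(image, grid, n_spokes, r_outer,
                               contrast_threshold = NULL, center = c(0, 0)) {
  stopifnot(inherits(grid, "sa_grid"))
  image <- as.matrix(image)
  if (!all(dim(image) == grid$n)) stop("image must be n x n on the grid")
  if (!is.null(contrast_threshold) &&
      (contrast_threshold <= 0 || contrast_threshold >= 1))
    stop("contrast_threshold must be in (0, 1)")
  half_spokes <- n_spokes / 2
  r_floor <- 2 * grid$dx * half_spokes / (2 * pi)   # period >= 2 pixels
  radii <- seq(r_outer * 0.98, r_floor, by = -grid$dx / 8)
  if (!length(radii)) return(NA_real_)
  m <- max(256L, 8L * n_spokes)
  ang <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  c0 <- grid$n / 2 + 1
  contrast_at <- function(r) {
    i <- c0 + (center[1] + r * cos(ang)) / grid$dx
    j <- c0 + (center[2] + r * sin(ang)) / grid$dx
    prof <- interp2(image, i, j)
    mu <- mean(prof)
    if (mu <= 0) return(0)
    2 * Mod(mean(prof * exp(-1i * half_spokes * ang))) / mu
  }
  contrasts <- vapply(radii, contrast_at, 0)
  if (is.null(contrast_threshold)) {
    plateau <- stats::median(contrasts[seq_len(max(1, length(radii) %/% 3))])
    contrast_threshold <- plateau / 2
    if (contrast_threshold <= 0) return(NA_real_)
  }
  ok <- contrasts >= contrast_threshold
  if (!ok[1]) return(NA_real_)
  last <- if (all(ok)) length(ok) else which(!ok)[1] - 1L
  2 * pi * radii[last] / half_spokes
}

#' Diffraction-limited resolution of a synthetic-aperture system
#'
#' The coherent synthetic aperture spans illumination plus collection
#' apertures, giving the two-sided diffraction limit
#' `Delta = lambda / (NA_ill + NA_col)`. Units follow `wavelength`.
#'
#' @param wavelength Vacuum wavelength (> 0), any length unit.
#' @param na_ill,na_col Illumination and collection numerical apertures (> 0).
#' @return The finest transferable period, in the units of `wavelength`.
#' @examples
#' diffraction_limit(785, 1.2, 1.2)  # 327.08 nm
#' @export
diffraction_limit <- function(wavelength, na_ill, na_col) {
  if (wavelength <= 0 || na_ill <= 0 || na_col <= 0)
    stop("wavelength and numerical apertures must be positive")
  wavelength / (na_ill + na_col)
}

#' Estimate the rigid translation between two images
#'
#' Local search of the discrete cross-correlation (within `max_px` pixels)
#' followed by quadratic sub-pixel interpolation. Used to locate a
#' reconstructed target relative to its reference layout: the tilt gauge of
#' the correction pair is a rigid image translation, so reconstructions are
#' recovered up to a (sub-)pixel shift.
#'
#' @param ref,img `n x n` real matrices on the same grid (`img` is `ref`
#'   translated by the returned amount, approximately).
#' @param grid The [make_grid()] grid.
#' @param max_px Search half-width in pixels (default 3).
#' @return Length-2 numeric: the translation in micrometres.
#' @export
estimate_image_shift <- function(ref, img, grid, max_px = 3L) {
  stopifnot(inherits(grid, "sa_grid"))
  n <- grid$n
  span <- -max_px:max_px
  score <- matrix(NA_real_, length(span), length(span))
  for (a in seq_along(span)) for (b in seq_along(span)) {
    dxp <- span[a]; dyp <- span[b]
    i <- max(1, 1 + dxp):min(n, n + dxp)
    j <- max(1, 1 + dyp):min(n, n + dyp)
    score[a, b] <- sum(img[i, j] * ref[i - dxp, j - dyp])
  }
  best <- which(score == max(score), arr.ind = TRUE)[1, ]
  sub <- function(v) {
    den <- v[1] - 2 * v[2] + v[3]
    if (den == 0) 0 else 0.5 * (v[1] - v[3]) / den
  }
  off <- c(0, 0)
  if (best[1] > 1 && best[1] < length(span))
    off[1] <- sub(score[(best[1] - 1):(best[1] + 1), best[2]])
  if (best[2] > 1 && best[2] < length(span))
    off[2] <- sub(score[best[1], (best[2] - 1):(best[2] + 1)])
  (c(span[best[1]], span[best[2]]) + off) * grid$dx
}
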