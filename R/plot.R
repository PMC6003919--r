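#' @export
plot.sa_object <- function(x, what = c("amplitude", "phase"), ...) {
  what <- match.arg(what)
  m <- if (what == "amplitude") Mod(x$transmittance) else
    Arg(x$transmittance)
  .plot_map(m, x$grid, main = paste("object", what), ...)
}

#' @export
plot.sa_pupil <- function(x, ...) {
  m <- x$phase
  m[!x$support] <- NA
  .plot_map(m, x$grid, main = sprintf("pupil phase (NA %g)", x$na),
            axes_unit = "rad/um", dk = TRUE, ...)
}

#' @export
plot.sa_spectrum <- function(x, log_scale = TRUE, ...) {
  m <- Mod(x$values)
  if (log_scale) m <- log10(m + max(m) * 1e-9)
  .plot_map(m, x$grid, main = "synthetic-aperture spectrum (|E_SA|)",
            axes_unit = "rad/um", dk = TRUE, ...)
}

#' @export
plot.sa_psf <- function(x, ...) {
  .plot_map(x$intensity, x$grid, main = "PSF intensity", ...)
}

#' @export
plot.sa_interferogram <- function(x, ...) {
  .plot_map(x$intensity, x$grid, main = "interferogram", ...)
}

#' Plot the convergence trace of a correction state
#'
#' Total synthetic-aperture intensity after each half-step (entry 1 is the
#' uncorrected intensity), on a linear scale.
#'
#' @param state An `sa_correction`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_intensity_trace <- function(state, ...) {
  stopifnot(inherits(state, "sa_correction"))
  graphics::plot(seq_along(state$intensity_trace) - 1, state$intensity_trace,
                 type = "b", xlab = "half-step",
                 ylab = "total SA intensity", ...)
}

.plot_map <- function(m, grid, main = "", axes_unit = "um", dk = FALSE, ...) {
  ax <- if (dk) grid_index(grid$n) * grid$dk else grid_coords(grid)
  graphics::image(ax, ax, m, asp = 1, main = main,
                  xlab = axes_unit, ylab = axes_unit,
                  col = grDevices::hcl.colors(64, "viridis"),
                  useRaster = TRUE, ...)
  invisible(NULL)
}
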