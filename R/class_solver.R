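#' Correction state of the CLASS iteration
#'
#' Holds the accumulated input correction `theta_i` (one value per
#' illumination, converging to `phi_i + g`), the accumulated output
#' correction `theta_o` (one value per output lattice point, converging to
#' `phi_o`), the total synthetic-aperture intensity after each completed
#' half-iteration, and the iteration count. Corrections are applied to the
#' data as `exp(-i theta)`, so each map accumulates toward `+` the aberration
#' it compensates.
#'
#' @param dataset The `sa_dataset` the state is defined on.
#' @return An object of class `sa_correction` with elements `theta_i`,
#'   `theta_o`, `intensity_trace`, `n_iter`, `converged`, `gauge`.
#' @export
new_correction_state <- function(dataset) {
  stopifnot(inherits(dataset, "sa_dataset"))
  structure(
    list(theta_i = rep(0, nrow(dataset$illums)),
         theta_o = rep(0, nrow(dataset$out_points)),
         intensity_trace = numeric(0),
         n_iter = 0L, converged = NA, gauge = NULL),
    class = "sa_correction")
}

#' @export
print.sa_correction <- function(x, ...) {
  cat(sprintf("<sa_correction> %d input / %d output phases, %d iterations%s\n",
              length(x$theta_i), length(x$theta_o), x$n_iter,
              if (isTRUE(x$converged)) " (converged)" else ""))
  if (length(x$intensity_trace))
    cat(sprintf("  total SA intensity: %.6g -> %.6g\n",
                x$intensity_trace[1],
                x$intensity_trace[length(x$intensity_trace)]))
  invisible(x)
}

# Dataset values with the accumulated corrections applied:
# V[o, i] = T[o, i] * exp(-i theta_o(o)) * exp(-i theta_i(i)).
corrected_values <- function(dataset, state) {
  dataset$values * (exp(-1i * state$theta_o) %o% exp(-1i * state$theta_i))
}

# Group-sum complex entries by Delta-k linear index into a length-n^2 vector.
sa_accumulate <- function(V, dk_lin, n) {
  s <- rowsum(cbind(as.vector(Re(V)), as.vector(Im(V))),
              group = as.vector(dk_lin), reorder = TRUE)
  sa <- complex(real = rep(0, n * n))
  sa[as.integer(rownames(s))] <- complex(real = s[, 1], imaginary = s[, 2])
  sa
}

#' Synthetic-aperture spectrum
#'
#' Coherently sums the corrected transmitted-field spectra over all
#' illuminations at equal momentum difference:
#'
#' \deqn{E_{SA}(\Delta k) = \sum_{k_i} E_o(k_i + \Delta k;\, k_i)\,
#'   e^{-i\theta_i(k_i)}\, e^{-i\theta_o(k_i+\Delta k)},}
#'
#' counting only pairs with `k_i` in the illumination support and
#' `k_i + Delta k` in the output support. Without aberration and drift the
#' result is proportional to the object spectrum times the per-bin pair
#' count; aberrations de-phase the sum and reduce its total intensity.
#'
#' @param dataset An `sa_dataset`.
#' @param state An `sa_correction` (defaults to the zero state).
#' @return An object of class `sa_spectrum`: list with `grid`, `values`
#'   (`n x n` complex over the Delta-k lattice), `weights` (`n x n` integer
#'   pair counts; values are zero wherever weights are zero).
#' @export
synth_aperture <- function(dataset, state = new_correction_state(dataset)) {
  stopifnot(inherits(dataset, "sa_dataset"), inherits(state, "sa_correction"))
  if (length(state$theta_i) != nrow(dataset$illums) ||
      length(state$theta_o) != nrow(dataset$out_points))
    stop("lattice mismatch: state was not built for this dataset")
  n <- dataset$grid$n
  dk_lin <- dataset_dk_linear(dataset$out_points, dataset$illums, n)
  V <- corrected_values(dataset, state)
  sa <- sa_accumulate(V, dk_lin, n)
  structure(
    list(grid = dataset$grid,
         values = matrix(sa, n, n),
         weights = matrix(tabulate(as.vector(dk_lin), nbins = n * n), n, n)),
    class = "sa_spectrum")
}

#' Total intensity of a synthetic-aperture spectrum
#'
#' The solver's objective: `sum(|E_SA(Delta k)|^2)` over the whole lattice.
#'
#' @param sa An `sa_spectrum`.
#' @return A non-negative scalar.
#' @export
total_intensity <- function(sa) {
  stopifnot(inherits(sa, "sa_spectrum"))
  sum(Mod(sa$values)^2)
}

# Shared correlation kernel of the two half-steps. Correlates every
# single-illumination (margin = 2, columns) or single-output-point
# (margin = 1, rows) slice of the corrected dataset against the full current
# synthetic aperture and returns the phase increments arg(<slice, E_SA>).
# With weighting = "consensus" (default) each Delta-k bin of E_SA is
# normalized to unit modulus first: the fixed points are unchanged (every
# pairwise dot product real) but each bin gets an equal vote, so the
# input/output split converges at a uniform geometric rate instead of being
# throttled by the object's DC power. "intensity" uses the raw aggregate.
# The self term of each slice is real and positive, so it biases the
# magnitude but never the argument; leave_one_out subtracts it (only
# meaningful with weighting = "intensity").
correlation_increments <- function(V, dk_lin, n, margin,
                                   weighting = "consensus",
                                   leave_one_out = FALSE) {
  sa <- sa_accumulate(V, dk_lin, n)
  saw <- sa
  if (weighting == "consensus") {
    m <- Mod(saw)
    nz <- m > 0
    saw[nz] <- saw[nz] / m[nz]
  }
  C <- V * Conj(matrix(saw[dk_lin], nrow(V), ncol(V)))
  cs <- if (margin == 2L) colSums(C) else rowSums(C)
  if (leave_one_out && weighting == "intensity") {
    self <- if (margin == 2L) colSums(Mod(V)^2) else rowSums(Mod(V)^2)
    cs <- cs - self
  }
  zero <- Mod(cs) == 0
  incr <- ifelse(zero, 0, Arg(cs))
  if (any(zero))
    warning(sprintf(
      "zero correlation for %d slice(s); their increments were set to 0",
      sum(zero)))
  list(increments = incr, intensity_before = sum(Mod(sa)^2))
}

#' One input-correction half-step
#'
#' For each illumination `k_i`, computes the phase of the scalar product of
#' that illumination's corrected spectrum with the current synthetic-aperture
#' spectrum,
#' `theta^(n)(k_i) = arg( sum_dk E~(k_i+dk; k_i) * Conj(E_SA(dk)) )`,
#' accumulates it into `theta_i`, and appends the post-update total intensity
#' to the trace. Aligning every slice's phase with the aggregate can only
#' increase the total intensity, which is the operational form of the
#' intensity-maximization objective.
#'
#' @param dataset An `sa_dataset`.
#' @param state An `sa_correction`.
#' @param weighting `"consensus"` (default) normalizes every Delta-k bin of
#'   the synthetic aperture to unit modulus before the dot product — same
#'   fixed points, equal per-bin votes, uniform convergence rate;
#'   `"intensity"` correlates against the raw aggregate (whose bins are
#'   weighted by the object's spectral power).
#' @param leave_one_out Correlate each slice against the aggregate minus its
#'   own contribution (useful for very small illumination counts; applies to
#'   `weighting = "intensity"`).
#' @return The updated `sa_correction`.
#' @export
input_step <- function(dataset, state = new_correction_state(dataset),
                       weighting = c("consensus", "intensity"),
                       leave_one_out = FALSE) {
  .half_step(dataset, state, "input", match.arg(weighting), leave_one_out)
}

#' One output-correction half-step
#'
#' Runs the input-correction rule on the phase-conjugated view of the
#' dataset, which swaps the roles of illumination and detection: the
#' resulting increments accumulate into `theta_o`. Operationally this is the
#' same correlation taken along rows of the transmission matrix instead of
#' columns ([phase_conjugate()] materializes the equivalent conjugated
#' dataset; a unit test asserts the two routes agree entrywise). Because
#' conjugation re-attaches the drift factor to what is now the output index,
#' the recovered `theta_o` is decoupled from the per-illumination drift.
#'
#' @inheritParams input_step
#' @return The updated `sa_correction`.
#' @export
output_step <- function(dataset, state = new_correction_state(dataset),
                        weighting = c("consensus", "intensity"),
                        leave_one_out = FALSE) {
  .half_step(dataset, state, "output", match.arg(weighting), leave_one_out)
}

.half_step <- function(dataset, state, side, weighting, leave_one_out) {
  stopifnot(inherits(dataset, "sa_dataset"), inherits(state, "sa_correction"))
  n <- dataset$grid$n
  dk_lin <- dataset_dk_linear(dataset$out_points, dataset$illums, n)
  V <- corrected_values(dataset, state)
  k <- correlation_increments(V, dk_lin, n,
                              margin = if (side == "input") 2L else 1L,
                              weighting = weighting,
                              leave_one_out = leave_one_out)
  if (side == "input") state$theta_i <- state$theta_i + k$increments
  else state$theta_o <- state$theta_o + k$increments
  V2 <- corrected_values(dataset, state)
  state$intensity_trace <- c(state$intensity_trace,
                             sum(Mod(sa_accumulate(V2, dk_lin, n))^2))
  state
}

#' Phase-conjugated view of a dataset
#'
#' Numerically reverses the optical axis: applies the accumulated input
#' correction, conjugates every entry, and transposes the roles of
#' illumination and detection in the transmission-matrix view. The entry at
#' (row `k_o`, column `k_i`) of the original dataset appears conjugated at
#' (row `k_i`, column `k_o`); the former output support becomes the
#' illumination support. The drift factor `exp(i g)` becomes `exp(-i g)` and
#' attaches to what is now the output index, so a subsequent correction step
#' on the conjugated view is drift-free.
#'
#' @param dataset An `sa_dataset`.
#' @param state Optional `sa_correction` whose `theta_i` is applied before
#'   conjugation (default: none).
#' @return An `sa_dataset` with swapped supports and conjugated values.
#' @export
phase_conjugate <- function(dataset, state = NULL) {
  stopifnot(inherits(dataset, "sa_dataset"))
  V <- dataset$values
  if (!is.null(state)) {
    stopifnot(inherits(state, "sa_correction"))
    V <- V * matrix(exp(-1i * state$theta_i),
                    nrow(V), ncol(V), byrow = TRUE)
  }
  grid <- dataset$grid
  illums_new <- dataset$out_points
  illums_new$kx <- illums_new$p * grid$dk
  illums_new$ky <- illums_new$q * grid$dk
  illums_new <- structure(illums_new, grid = grid,
                          na_ill = dataset$meta$na_col,
                          class = c("sa_illuminations", "data.frame"))
  out_new <- as.data.frame(dataset$illums)[, c("p", "q")]
  structure(
    list(grid = grid, illums = illums_new, out_points = out_new,
         values = Conj(t(V)), configuration = dataset$configuration,
         meta = list(na_ill = dataset$meta$na_col,
                     na_col = dataset$meta$na_ill,
                     provenance = paste0(dataset$meta$provenance,
                                         " (phase conjugated)"))),
    class = "sa_dataset")
}

#' Run the iterative CLASS aberration-correction solver
#'
#' Alternates input- and output-correction half-steps, each of which aligns
#' every single-illumination (or single-output-point) spectrum with the
#' current synthetic aperture, monotonically increasing the total
#' synthetic-aperture intensity. Iteration stops when the relative intensity
#' change over a full iteration drops below `rel_tol` or after `max_iter`
#' iterations; non-convergence is reported in the returned state, not as an
#' error. The returned state is gauge-normalized ([remove_gauge()]): pistons
#' are removed so both maps vanish at the origin, and the shared tilt pair
#' (a rigid image translation) is removed by least squares.
#'
#' @param dataset An `sa_dataset`.
#' @param max_iter Maximum number of full iterations (default 15).
#' @param rel_tol Relative intensity-change stopping tolerance (default 1e-6).
#' @param order Which half-step runs first, `c("input", "output")` (default)
#'   or `c("output", "input")`.
#' @param weighting,leave_one_out Passed to the half-steps (see
#'   [input_step()]).
#' @return A list with components `state` (`sa_correction`, gauge-normalized,
#'   with the full intensity trace: entry 1 is the uncorrected intensity,
#'   then one entry per half-step) and `sa` (the final `sa_spectrum`).
#' @examples
#' g <- make_grid(4, 32, 0.785)
#' ill <- enumerate_illuminations(g, 1.0)
#' ds <- simulate_dataset(make_point_object(g), make_ideal_pupil(g, 1.0),
#'                        make_ideal_pupil(g, 1.0), NULL, ill)
#' fit <- run_class(ds, max_iter = 2)
#' fit$state$converged
#' @export
run_class <- function(dataset, max_iter = 15L, rel_tol = 1e-6,
                      order = c("input", "output"),
                      weighting = c("consensus", "intensity"),
                      leave_one_out = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(dataset, "sa_dataset"), max_iter >= 1)
  order <- match.arg(order, c("input", "output"), several.ok = TRUE)
  if (length(order) == 1L)
    order <- c(order, setdiff(c("input", "output"), order))
  n <- dataset$grid$n
  dk_lin <- dataset_dk_linear(dataset$out_points, dataset$illums, n)
  state <- new_correction_state(dataset)

  V <- corrected_values(dataset, state)
  I_prev <- sum(Mod(sa_accumulate(V, dk_lin, n))^2)
  state$intensity_trace <- I_prev
  for (it in seq_len(max_iter)) {
    for (side in order) {
      k <- correlation_increments(V, dk_lin, n,
                                  margin = if (side == "input") 2L else 1L,
                                  weighting = weighting,
                                  leave_one_out = leave_one_out)
      if (side == "input") {
        state$theta_i <- state$theta_i + k$increments
        V <- V * matrix(exp(-1i * k$increments), nrow(V), ncol(V),
                        byrow = TRUE)
      } else {
        state$theta_o <- state$theta_o + k$increments
        V <- V * exp(-1i * k$increments)
      }
      state$intensity_trace <- c(state$intensity_trace,
                                 sum(Mod(sa_accumulate(V, dk_lin, n))^2))
    }
    state$n_iter <- it
    I_now <- state$intensity_trace[length(state$intensity_trace)]
    if (I_prev > 0 && abs(I_now - I_prev) / I_prev < rel_tol) {
      state$converged <- TRUE
      break
    }
    I_prev <- I_now
  }
  if (!isTRUE(state$converged)) state$converged <- FALSE
  ng <- remove_gauge(state$theta_i, state$theta_o,
                     dataset$illums, dataset$out_points)
  state$theta_i <- ng$theta_i
  state$theta_o <- ng$theta_o
  state$gauge <- ng[c("piston_i", "piston_o", "tilt")]
  list(state = state, sa = synth_aperture(dataset, state))
}

#' Remove the gauge freedoms of a correction pair
#'
#' The synthetic-aperture objective is blind to a global phase (piston) on
#' each map and to the paired tilt `(+a . k` on `theta_i`, `-a . k` on
#' `theta_o)`, which corresponds to a rigid translation of the reconstructed
#' image. This normalization subtracts each map's value at the lattice
#' origin and removes the shared tilt, estimated by least squares as half
#' the difference of the two maps' fitted tilts. Applying it twice is a
#' no-op.
#'
#' @param theta_i Numeric vector of input corrections, ordered as `illums`.
#' @param theta_o Numeric vector of output corrections, ordered as
#'   `out_points`.
#' @param illums Illumination lattice (data.frame with `p`, `q`).
#' @param out_points Output-support lattice (data.frame with `p`, `q`).
#' @return A list with normalized `theta_i`, `theta_o`, and the removed
#'   `piston_i`, `piston_o`, `tilt` (length-2 vector, radians per lattice
#'   unit).
#' @export
remove_gauge <- function(theta_i, theta_o, illums, out_points) {
  stopifnot(length(theta_i) == nrow(illums),
            length(theta_o) == nrow(out_points))
  fit_tilt <- function(th, pts) {
    X <- cbind(1, pts$p, pts$q)
    qr.solve(X, th)[2:3]
  }
  t_i <- fit_tilt(theta_i, illums)
  t_o <- fit_tilt(theta_o, out_points)
  a <- (t_i - t_o) / 2
  theta_i <- theta_i - (illums$p * a[1] + illums$q * a[2])
  theta_o <- theta_o + (out_points$p * a[1] + out_points$q * a[2])
  oi <- which(illums$p == 0 & illums$q == 0)
  oo <- which(out_points$p == 0 & out_points$q == 0)
  piston_i <- if (length(oi)) theta_i[oi[1]] else 0
  piston_o <- if (length(oo)) theta_o[oo[1]] else 0
  list(theta_i = theta_i - piston_i, theta_o = theta_o - piston_o,
       piston_i = piston_i, piston_o = piston_o, tilt = unname(a))
}

#' Reconstruct a real-space image from a synthetic-aperture spectrum
#'
#' Inverse transform of the synthetic-aperture spectrum. With
#' `normalize = "weights"` each Delta-k bin is divided by its contributing
#' pair count first, equalizing the transfer function to that of an ideal
#' coherent aperture of radius `(na_ill + na_col) * k0`; with `"none"` the
#' raw (apodized) sum is transformed as-is.
#'
#' @param sa An `sa_spectrum`.
#' @param normalize `"weights"` (default) or `"none"`.
#' @param oversample Integer upsampling factor (default 1). The spectrum is
#'   zero-padded to an `oversample * n` lattice before inversion, giving a
#'   sinc-interpolated field on a finer pixel grid. The intensity of a field
#'   band-limited at `K` has spectral content out to `2K`, so quantitative
#'   contrast analysis of `Mod(.)^2` (e.g. [siemens_resolution()]) needs
#'   `oversample >= 2` to avoid aliasing the intensity.
#' @return Complex image matrix of side `oversample * n` (take `Mod(.)^2`
#'   for intensity); it lives on the grid
#'   `make_grid(fov, oversample * n, wavelength)`.
#' @export
sa_image <- function(sa, normalize = c("weights", "none"), oversample = 1L) {
  stopifnot(inherits(sa, "sa_spectrum"), oversample >= 1)
  normalize <- match.arg(normalize)
  oversample <- as.integer(oversample)
  v <- sa$values
  if (normalize == "weights") {
    w <- sa$weights
    v[w > 0] <- v[w > 0] / w[w > 0]
  }
  if (oversample > 1L) {
    n <- nrow(v)
    nb <- oversample * n
    big <- matrix(0 + 0i, nb, nb)
    lo <- nb / 2 - n / 2 + 1
    big[lo:(lo + n - 1), lo:(lo + n - 1)] <- v
    v <- big * oversample
  }
  fft_inverse(v)
}
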