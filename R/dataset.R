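#' Angle-scanned transmission dataset (forward model)
#'
#' Simulates the complex transmitted-field spectra `E_o(k_o; k_i)` of a thin
#' object measured through an aberrated input pupil and an aberrated output
#' pupil with per-illumination phase drift. For each illumination wavevector
#' `k_i` and each output lattice point `k_o` inside the collection aperture,
#'
#' \deqn{E_o(k_o; k_i) = P_o^a(k_o) \, O(k_o - k_i) \, P_i^a(k_i) \, e^{i g(k_i)},}
#'
#' where `O` is the object's angular spectrum, `P^a = exp(i phi)` are the
#' unit-amplitude pupil transfer functions and `g` the drift. Spectra are zero
#' outside the output-pupil support. The momentum difference
#' `Delta k = k_o - k_i` must stay on the lattice, so the constructor requires
#' `(na_ill + na_col) * k0` to be within the grid Nyquist frequency.
#'
#' @param obj An [make_object()] object field (the sample).
#' @param pupil_in,pupil_out [make_ideal_pupil()] /
#'   [make_condenser_aberration()] pupils for illumination and collection.
#' @param drift An [sample_drift()] drift (or `NULL` for none).
#' @param illums An [enumerate_illuminations()] set; every illumination must
#'   lie inside the input-pupil support.
#' @return An object of class `sa_dataset`: list with `grid`, `illums`,
#'   `out_points` (output-support lattice as a data.frame), `values`
#'   (complex matrix, rows = output points, columns = illuminations),
#'   `configuration` (`"sample_plane"` or `"conjugate_plane"`), and `meta`
#'   (`na_ill`, `na_col`, `provenance`).
#' @seealso [simulate_conjugate_dataset()] for the second measurement
#'   geometry, [synth_aperture()] for the synthetic-aperture sum.
#' @export
simulate_dataset <- function(obj, pupil_in, pupil_out, drift = NULL, illums) {
  .simulate(obj, pupil_in, pupil_out, drift, illums,
            configuration = "sample_plane")
}

#' Conjugate-plane dataset for input/drift separation
#'
#' Simulates the second measurement configuration in which a test target sits
#' at the conjugate image plane before the input condenser: the system then
#' has no input-side aberration and the two pupil phases combine on the
#' output side,
#'
#' \deqn{E'(k_o; k_i) = P_o^a(k_o) P_i^a(k_o) \, O'(k_o - k_i) \, e^{i g'(k_i)}.}
#'
#' Running the solver on such a dataset recovers `phi_i + phi_o` as its output
#' correction, so subtracting the output correction of a sample-plane run
#' isolates the pure input aberration ([separate_input()]).
#'
#' @inheritParams simulate_dataset
#' @param test_obj The test target placed at the conjugate plane.
#' @param drift2 Drift of this second acquisition (independent of the first).
#' @return An `sa_dataset` with `configuration = "conjugate_plane"`.
#' @export
simulate_conjugate_dataset <- function(test_obj, pupil_in, pupil_out,
                                       drift2 = NULL, illums) {
  .simulate(test_obj, pupil_in, pupil_out, drift2, illums,
            configuration = "conjugate_plane")
}

.simulate <- function(obj, pupil_in, pupil_out, drift, illums, configuration) {
  stopifnot(inherits(obj, "sa_object"),
            inherits(pupil_in, "sa_pupil"),
            inherits(pupil_out, "sa_pupil"),
            inherits(illums, "sa_illuminations"))
  grid <- obj$grid
  stop_if_grid_mismatch(grid, pupil_in$grid, "object and input pupil")
  stop_if_grid_mismatch(grid, pupil_out$grid, "object and output pupil")
  stop_if_grid_mismatch(grid, attr(illums, "grid"), "object and illuminations")
  n <- grid$n
  na_ill <- attr(illums, "na_ill")
  na_col <- pupil_out$na
  if ((na_ill + na_col) * grid$k0 > grid$k_nyquist + 1e-9)
    stop(paste0("sizing error: (na_ill + na_col) * k0 exceeds the grid ",
                "Nyquist frequency; the momentum-difference lattice would wrap"))
  ill_lin <- lattice_linear(illums$p, illums$q, n)
  if (!all(pupil_in$support[ill_lin]))
    stop("illumination outside the input-pupil support")

  out <- output_support_points(grid, na_col)
  out_lin <- lattice_linear(out$p, out$q, n)
  O <- object_spectrum(obj)
  dk_lin <- dataset_dk_linear(out, illums, n)

  if (is.null(drift)) {
    g <- rep(0, nrow(illums))
  } else {
    stopifnot(inherits(drift, "sa_drift"))
    if (length(drift$g) != nrow(illums))
      stop("drift vector length does not match the illumination count")
    g <- drift$g
  }
  if (configuration == "sample_plane") {
    row_fac <- exp(1i * pupil_out$phase[out_lin])
    col_fac <- exp(1i * (pupil_in$phase[ill_lin] + g))
  } else {
    # conjugate plane: the combined product pupil acts at the output
    # wavevector; its support is the intersection of the two pupils
    row_fac <- exp(1i * (pupil_out$phase[out_lin] + pupil_in$phase[out_lin])) *
      as.numeric(pupil_in$support[out_lin])
    col_fac <- exp(1i * g)
  }
  values <- matrix(O[dk_lin], nrow(out), nrow(illums)) *
    (row_fac %o% col_fac)
  structure(
    list(grid = grid, illums = illums, out_points = out, values = values,
         configuration = configuration,
         meta = list(na_ill = na_ill, na_col = na_col,
                     provenance = "saclass forward model")),
    class = "sa_dataset")
}

# Linear indices (into an n x n centered array) of Delta k = k_o - k_i for
# every (output point, illumination) pair; an n_out x n_ill integer matrix.
dataset_dk_linear <- function(out, illums, n) {
  dp <- outer(out$p, illums$p, "-")
  dq <- outer(out$q, illums$q, "-")
  matrix(lattice_linear(as.vector(dp), as.vector(dq), n),
         nrow(out), nrow(illums))
}

#' @export
print.sa_dataset <- function(x, ...) {
  cat(sprintf(
    "<sa_dataset> %s: %d illuminations (NA %g) x %d output points (NA %g)\n",
    x$configuration, nrow(x$illums), x$meta$na_ill,
    nrow(x$out_points), x$meta$na_col))
  invisible(x)
}

#' Extract one measured spectrum as a full-lattice matrix
#'
#' Returns the spectrum of illumination `j` embedded in the full `n x n`
#' centered frequency lattice (zero outside the output-pupil support).
#'
#' @param dataset An `sa_dataset`.
#' @param j Illumination index (column), 1-based.
#' @return `n x n` complex matrix.
#' @export
get_spectrum <- function(dataset, j) {
  stopifnot(inherits(dataset, "sa_dataset"))
  n <- dataset$grid$n
  s <- matrix(0 + 0i, n, n)
  s[lattice_linear(dataset$out_points$p, dataset$out_points$q, n)] <-
    dataset$values[, j]
  s
}

#' Matrix view of a transmission dataset
#'
#' Re-expresses the dataset as an explicit transmission matrix
#' `T[k_o, k_i]` with row and column lattice tables. The round trip through
#' [matrix_as_dataset()] is lossless.
#'
#' @param dataset An `sa_dataset`.
#' @return An object of class `sa_tmatrix`: list with `rows` (output lattice
#'   data.frame), `cols` (illumination lattice data.frame), `values`
#'   (complex matrix), `grid`, `configuration`, `meta`.
#' @export
dataset_as_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "sa_dataset"))
  if (nrow(dataset$illums) == 0L) stop("empty dataset")
  structure(
    list(rows = dataset$out_points,
         cols = as.data.frame(dataset$illums),
         values = dataset$values,
         grid = dataset$grid,
         configuration = dataset$configuration,
         meta = dataset$meta),
    class = "sa_tmatrix")
}

#' @rdname dataset_as_matrix
#' @param tm An `sa_tmatrix`.
#' @export
matrix_as_dataset <- function(tm) {
  stopifnot(inherits(tm, "sa_tmatrix"))
  illums <- tm$cols
  illums$kx <- illums$p * tm$grid$dk
  illums$ky <- illums$q * tm$grid$dk
  illums <- structure(illums, grid = tm$grid, na_ill = tm$meta$na_ill,
                      class = c("sa_illuminations", "data.frame"))
  structure(
    list(grid = tm$grid, illums = illums, out_points = tm$rows,
         values = tm$values, configuration = tm$configuration, meta = tm$meta),
    class = "sa_dataset")
}
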