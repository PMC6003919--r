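test_that("forward model matches a naive per-entry three-factor oracle", {
  sc <- small_scene()
  ds <- sc$ds
  n <- sc$g$n
  O <- object_spectrum(sc$obj)
  at <- function(m, p, q) m[p + n / 2 + 1, q + n / 2 + 1]
  set.seed(3)
  rows <- sample(nrow(ds$out_points), 40)
  cols <- sample(nrow(sc$ill), 10)
  for (j in cols) for (i in rows) {
    po <- at(exp(1i * sc$pout$phase), ds$out_points$p[i], ds$out_points$q[i])
    pi_ <- at(exp(1i * sc$pin$phase), sc$ill$p[j], sc$ill$q[j])
    Odk <- at(O, ds$out_points$p[i] - sc$ill$p[j],
              ds$out_points$q[i] - sc$ill$q[j])
    expect_equal(ds$values[i, j], po * Odk * pi_ * exp(1i * sc$dr$g[j]),
                 tolerance = 1e-12)
  }
})

test_that("with ideal pupils and no drift each spectrum is the shifted object spectrum", {
  g <- make_grid(4, 32, 0.785)
  ill <- enumerate_illuminations(g, 0.8)
  pup <- make_ideal_pupil(g, 0.8)
  obj <- make_phase_blobs(g, 6, 1, seed = 9)
  ds <- simulate_dataset(obj, pup, pup, NULL, ill)
  O <- object_spectrum(obj)
  n <- g$n
  j <- which(ill$p == 2 & ill$q == -3)
  S <- get_spectrum(ds, j)
  for (i in sample(nrow(ds$out_points), 30)) {
    p <- ds$out_points$p[i]; q <- ds$out_points$q[i]
    expect_equal(S[p + 17, q + 17], O[p - 2 + 17, q + 3 + 17],
                 tolerance = 1e-12)
  }
})

test_that("conjugate-plane model multiplies the pupils on the output side", {
  g <- make_grid(4, 32, 0.785)
  ill <- enumerate_illuminations(g, 0.9)
  phi <- make_condenser_aberration(g, 0.9, c(0.7, 1.1))
  obj <- make_siemens_star(g, 6, 1.4)
  dr <- sample_drift(ill, 2, seed = 4)
  # identical pupils: effective output phase is 2*phi
  ds2 <- simulate_conjugate_dataset(obj, phi, phi, dr, ill)
  ideal <- make_ideal_pupil(g, 0.9)
  twophi <- ideal
  twophi$phase <- 2 * phi$phase
  ds_ref <- simulate_dataset(obj, ideal, twophi, dr, ill)
  expect_equal(ds2$values, ds_ref$values, tolerance = 1e-12)
  expect_identical(ds2$configuration, "conjugate_plane")
  # with an aberration-free input pupil both configurations coincide
  dsa <- simulate_conjugate_dataset(obj, ideal, phi, dr, ill)
  dsb <- simulate_dataset(obj, ideal, phi, dr, ill)
  expect_equal(dsa$values, dsb$values, tolerance = 1e-12)
})

test_that("matrix view round-trips losslessly", {
  sc <- small_scene()
  tm <- dataset_as_matrix(sc$ds)
  expect_equal(tm$values, sc$ds$values)
  back <- matrix_as_dataset(tm)
  expect_equal(back$values, sc$ds$values)
  expect_identical(back$configuration, sc$ds$configuration)
  expect_equal(as.data.frame(back$illums), as.data.frame(sc$ds$illums))
  # single illumination -> single-column matrix
  g <- make_grid(4, 32, 0.785)
  one <- enumerate_illuminations(g, 0.5 * g$dk / g$k0)
  ds1 <- simulate_dataset(make_point_object(g), make_ideal_pupil(g, 1),
                          make_ideal_pupil(g, 1), NULL, one)
  expect_equal(ncol(dataset_as_matrix(ds1)$values), 1L)
})

test_that("sizing and support violations are rejected", {
  g <- make_grid(4, 32, 0.785)
  g2 <- make_grid(5, 32, 0.785)
  ill <- enumerate_illuminations(g, 1.0)
  pup <- make_ideal_pupil(g, 1.0)
  obj <- make_object(g2, matrix(1, 32, 32))
  expect_error(simulate_dataset(obj, pup, pup, NULL, ill), "grid mismatch")
  # illumination outside the input support
  small_pup <- make_ideal_pupil(g, 0.5)
  expect_error(
    simulate_dataset(make_point_object(g), small_pup, pup, NULL, ill),
    "outside the input-pupil support")
  # synthetic aperture would wrap the lattice
  big <- make_ideal_pupil(g, 1.95)
  ill_big <- enumerate_illuminations(g, 1.95)
  expect_error(
    simulate_dataset(make_point_object(g), big, big, NULL, ill_big),
    "Nyquist")
})
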