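test_that("synthetic aperture matches a naive double-loop oracle", {
  g <- make_grid(4, 32, 0.785)
  ill <- enumerate_illuminations(g, 0.6)
  pin <- make_condenser_aberration(g, 0.6, c(1, 1))
  pout <- make_condenser_aberration(g, 0.7, c(0.5, 1))
  obj <- make_phase_blobs(g, 5, 1, seed = 2)
  dr <- sample_drift(ill, pi, 8)
  ds <- simulate_dataset(obj, pin, pout, dr, ill)
  st <- new_correction_state(ds)
  set.seed(21)
  st$theta_i <- runif(length(st$theta_i), -pi, pi)
  st$theta_o <- runif(length(st$theta_o), -pi, pi)
  sa <- synth_aperture(ds, st)
  n <- g$n
  want <- matrix(0 + 0i, n, n)
  wcount <- matrix(0L, n, n)
  for (j in seq_len(nrow(ill))) for (i in seq_len(nrow(ds$out_points))) {
    dp <- ds$out_points$p[i] - ill$p[j]
    dq <- ds$out_points$q[i] - ill$q[j]
    want[dp + 17, dq + 17] <- want[dp + 17, dq + 17] +
      ds$values[i, j] * exp(-1i * st$theta_i[j]) * exp(-1i * st$theta_o[i])
    wcount[dp + 17, dq + 17] <- wcount[dp + 17, dq + 17] + 1L
  }
  expect_equal(sa$values, want, tolerance = 1e-12)
  expect_identical(sa$weights, wcount)
  expect_true(all(sa$values[sa$weights == 0] == 0))
  expect_equal(total_intensity(sa), sum(Mod(want)^2), tolerance = 1e-12)
})

test_that("single illumination gives the re-indexed single spectrum", {
  g <- make_grid(4, 32, 0.785)
  one <- enumerate_illuminations(g, 0.5 * g$dk / g$k0)
  ds <- simulate_dataset(make_phase_blobs(g, 4, 1, seed = 3),
                         make_ideal_pupil(g, 1), make_ideal_pupil(g, 1),
                         NULL, one)
  sa <- synth_aperture(ds)
  expect_equal(sa$values, get_spectrum(ds, 1), tolerance = 1e-12)
})

test_that("an ideal point-object synthetic aperture has |E_SA| proportional to weights", {
  g <- make_grid(4, 32, 0.785)
  ill <- enumerate_illuminations(g, 0.8)
  pup <- make_ideal_pupil(g, 0.8)
  ds <- simulate_dataset(make_point_object(g), pup, pup, NULL, ill)
  sa <- synth_aperture(ds)
  nz <- sa$weights > 0
  ratio <- Mod(sa$values[nz]) / sa$weights[nz]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
})

test_that("aberration and drift can only lower the total SA intensity", {
  g <- make_grid(4, 32, 0.785)
  ill <- enumerate_illuminations(g, 1.0)
  pup0 <- make_ideal_pupil(g, 1.0)
  obj <- make_siemens_star(g, 8, 1.6)
  I_ideal <- total_intensity(synth_aperture(
    simulate_dataset(obj, pup0, pup0, NULL, ill)))
  for (seed in 1:5) {
    set.seed(seed)
    pin <- make_condenser_aberration(g, 1.0, runif(3, -3, 3))
    pout <- make_condenser_aberration(g, 1.0, runif(3, -3, 3))
    dr <- sample_drift(ill, pi, seed)
    I_ab <- total_intensity(synth_aperture(
      simulate_dataset(obj, pin, pout, dr, ill)))
    expect_lte(I_ab, I_ideal * (1 + 1e-9))
  }
})

test_that("input correction recovers the drift on an ideal point object", {
  g <- make_grid(4, 32, 0.785)
  ill <- enumerate_illuminations(g, 0.9)
  pup <- make_ideal_pupil(g, 0.9)
  # one half-step contracts a small drift strongly ...
  dr_s <- sample_drift(ill, 0.3, 17)
  ds_s <- simulate_dataset(make_point_object(g), pup, pup, dr_s, ill)
  st <- input_step(ds_s)
  expect_length(st$intensity_trace, 1L)
  expect_lt(circular_rms_phase_error(st$theta_i, dr_s$g),
            0.35 * sd(dr_s$g))
  # ... and the converged solver recovers even a +-pi drift to machine level
  dr <- sample_drift(ill, pi, 17)
  ds <- simulate_dataset(make_point_object(g), pup, pup, dr, ill)
  fit <- run_class(ds, max_iter = 30, rel_tol = 1e-14)
  expect_lt(circular_rms_phase_error(fit$state$theta_i, dr$g, ill), 1e-7)
})

test_that("a converged state is a fixed point of both half-steps", {
  sc <- small_scene()
  fit <- run_class(sc$ds, max_iter = 40, rel_tol = 0)
  st_i <- input_step(sc$ds, fit$state)
  st_o <- output_step(sc$ds, fit$state)
  expect_lt(max(abs(st_i$theta_i - fit$state$theta_i)), 1e-7)
  expect_lt(max(abs(st_o$theta_o - fit$state$theta_o)), 1e-7)
})

test_that("half-steps never decrease the total SA intensity", {
  sc <- small_scene()
  st <- new_correction_state(sc$ds)
  I <- total_intensity(synth_aperture(sc$ds, st))
  for (k in 1:6) {
    st <- if (k %% 2 == 1) input_step(sc$ds, st) else output_step(sc$ds, st)
    I_new <- st$intensity_trace[length(st$intensity_trace)]
    expect_gte(I_new, I * (1 - 1e-9))
    I <- I_new
  }
})

test_that("phase conjugation is conj + transpose with the input correction applied", {
  sc <- small_scene()
  st <- new_correction_state(sc$ds)
  set.seed(5)
  st$theta_i <- runif(length(st$theta_i), -pi, pi)
  pc <- phase_conjugate(sc$ds, st)
  # index-bookkeeping oracle on random entries
  set.seed(6)
  for (k in 1:50) {
    i <- sample(nrow(sc$ds$out_points), 1)
    j <- sample(nrow(sc$ill), 1)
    expect_equal(pc$values[j, i],
                 Conj(sc$ds$values[i, j] * exp(-1i * st$theta_i[j])),
                 tolerance = 1e-12)
  }
  expect_equal(as.data.frame(pc$illums)[, c("p", "q")],
               sc$ds$out_points[, c("p", "q")])
  # double conjugation with zero corrections is the identity
  pc2 <- phase_conjugate(phase_conjugate(sc$ds))
  expect_equal(pc2$values, sc$ds$values, tolerance = 1e-12)
})

test_that("output step equals the input rule run on the phase-conjugated view", {
  sc <- small_scene()
  st <- new_correction_state(sc$ds)
  set.seed(31)
  st$theta_i <- runif(length(st$theta_i), -1, 1)
  st$theta_o <- runif(length(st$theta_o), -1, 1)
  st_direct <- output_step(sc$ds, st)
  # conjugated route: the pc view's column correction is -theta_o, and its
  # increments accumulate with opposite sign into theta_o
  pc <- phase_conjugate(sc$ds, st)
  pc_state <- new_correction_state(pc)
  pc_state$theta_i <- -st$theta_o
  pc_after <- input_step(pc, pc_state)
  incr_pc <- pc_after$theta_i - pc_state$theta_i
  expect_equal(st_direct$theta_o, st$theta_o - incr_pc, tolerance = 1e-10)
})

test_that("output correction recovers a pure output aberration on a point object", {
  g <- make_grid(4, 32, 0.785)
  ill <- enumerate_illuminations(g, 0.9)
  pin <- make_ideal_pupil(g, 0.9)
  pout <- make_condenser_aberration(g, 0.9, c(0.4, 0.8))
  ds <- simulate_dataset(make_point_object(g), pin, pout, NULL, ill)
  out_lin <- lattice_index_of(ds$out_points, g$n)
  truth <- pout$phase[out_lin]
  st <- output_step(ds)
  expect_lt(circular_rms_phase_error(st$theta_o, truth), 0.1)
  fit <- run_class(ds, max_iter = 30, rel_tol = 1e-14)
  expect_lt(circular_rms_phase_error(fit$state$theta_o, truth,
                                     ds$out_points), 1e-8)
})

test_that("the solver is the identity on aberration-free data", {
  g <- make_grid(4, 32, 0.785)
  ill <- enumerate_illuminations(g, 1.0)
  pup <- make_ideal_pupil(g, 1.0)
  ds <- simulate_dataset(make_siemens_star(g, 8, 1.6), pup, pup, NULL, ill)
  sa0 <- synth_aperture(ds)
  fit <- run_class(ds)
  expect_true(fit$state$converged)
  expect_equal(fit$state$n_iter, 1L)
  expect_lt(max(abs(fit$state$theta_i)), 1e-9)
  expect_lt(max(abs(fit$state$theta_o)), 1e-9)
  expect_equal(fit$sa$values, sa0$values, tolerance = 1e-9)
})

test_that("the solver recovers ground-truth aberrations on the small scene", {
  sc <- small_scene()
  fit <- run_class(sc$ds, max_iter = 15, rel_tol = 1e-8)
  n <- sc$g$n
  ill_lin <- lattice_index_of(sc$ill, n)
  out_lin <- lattice_index_of(sc$ds$out_points, n)
  expect_lt(circular_rms_phase_error(
    fit$state$theta_i, sc$pin$phase[ill_lin] + sc$dr$g, sc$ill), 0.05)
  expect_lt(circular_rms_phase_error(
    fit$state$theta_o, sc$pout$phase[out_lin], sc$ds$out_points), 0.05)
  tr <- fit$state$intensity_trace
  expect_true(all(diff(tr) >= -1e-9 * tr[-1]))
})

test_that("gauge removal is idempotent and inverts an injected tilt", {
  sc <- small_scene()
  ill <- as.data.frame(sc$ill)[, c("p", "q")]
  out <- sc$ds$out_points[, c("p", "q")]
  set.seed(12)
  th_i <- rnorm(nrow(ill)); th_o <- rnorm(nrow(out))
  g1 <- remove_gauge(th_i, th_o, ill, out)
  g2 <- remove_gauge(g1$theta_i, g1$theta_o, ill, out)
  expect_equal(g2$theta_i, g1$theta_i, tolerance = 1e-10)
  expect_equal(g2$theta_o, g1$theta_o, tolerance = 1e-10)
  expect_equal(g2$tilt, c(0, 0), tolerance = 1e-10)
  a <- c(0.13, -0.07)
  g3 <- remove_gauge(g1$theta_i + a[1] * ill$p + a[2] * ill$q,
                     g1$theta_o - a[1] * out$p - a[2] * out$q, ill, out)
  expect_equal(g3$theta_i, g1$theta_i, tolerance = 1e-10)
  expect_equal(g3$theta_o, g1$theta_o, tolerance = 1e-10)
  expect_equal(g3$tilt, a, tolerance = 1e-10)
})

test_that("weight-normalized reconstruction inverts an ideal measurement", {
  g <- make_grid(4, 32, 0.785)
  ill <- enumerate_illuminations(g, 1.0)
  pup <- make_ideal_pupil(g, 1.0)
  # band-limited object fully inside the synthetic aperture
  set.seed(44)
  n <- g$n
  idx <- seq.int(-n / 2, n / 2 - 1)
  P <- matrix(idx, n, n); Q <- matrix(idx, n, n, byrow = TRUE)
  spec <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  spec[P^2 + Q^2 > 4^2] <- 0
  obj <- make_object(g, fft_inverse(spec))
  ds <- simulate_dataset(obj, pup, pup, NULL, ill)
  img <- sa_image(synth_aperture(ds), normalize = "weights")
  expect_equal(img, obj$transmittance, tolerance = 1e-9)
})
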