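# saclass

Computational aberration correction for transmission-mode synthetic-aperture
holographic microscopy (the CLASS method: closed-loop accumulation of single
scattering).

## The problem

Condenser lenses give the millimetre working distances needed to image
through thick sample mounts, but used as objectives they carry severe pupil
aberrations, steepest beyond ~0.8 NA. In an angle-scanned transmission
holographic microscope the recorded spectra are, per illumination wavevector
$k^i$,

$$E_o(k^o; k^i) = P_o^a(k^o)\,O(k^o - k^i)\,P_i^a(k^i)\,e^{i g(k^i)},$$

with unit-amplitude pupils $P^a_{i,o} = e^{i\varphi_{i,o}}$ on
$|k| \le \mathrm{NA}\,k_0$, object spectrum $O$, and an uncontrolled global
phase drift $g(k^i)$ per acquisition. The synthetic-aperture spectrum
$E_{SA}(\Delta k) = \sum_{k^i} E_o(k^i + \Delta k; k^i)$ would reach the
two-sided diffraction limit $\Delta = \lambda/(\mathrm{NA}_{ill} +
\mathrm{NA}_{col})$, but aberration and drift de-phase the sum and destroy
the reconstruction.

`saclass` recovers both pupil phases *from the data alone* by iteratively
maximizing the total SA intensity $\sum_{\Delta k} |E_{SA}(\Delta k)|^2$:
an input half-step aligns each single-illumination spectrum with the
aggregate ($\theta_i \to \varphi_i + g$), and an output half-step applies
the same rule to the numerically phase-conjugated data
($\theta_o \to \varphi_o$, decoupled from the drift). A second measurement
configuration — the target at the conjugate image plane before the input
condenser, where the two pupils multiply on the output side — lets the pure
input aberration be isolated as $\theta_o' - \theta_o \to \varphi_i$.
A full forward simulator (objects, condenser-like aberrations, drift,
off-axis interferograms) makes every stage testable end to end, and PSF /
Strehl / FWHM / Airy-fit / Siemens-star metrics quantify the result. The
intended users are researchers in computational adaptive optics and
quantitative phase imaging.

## Worked example

Simulate the reference scenario — 12.8 µm field, 128² pixels, λ = 785 nm,
both pupils NA 1.2 with radial aberrations summing to 6 rad at the pupil
edge, 36-spoke Siemens star, drift uniform in ±π — and solve it:

```r
library(saclass)

g <- make_grid(fov = 12.8, n = 128, wavelength = 0.785)
ill <- enumerate_illuminations(g, na_ill = 1.2)          # 1201 plane waves
pupil_in  <- make_condenser_aberration(g, 1.2, radial_coeffs = c(1, 2, 3))
pupil_out <- make_condenser_aberration(g, 1.2, radial_coeffs = c(0.5, 1.5, 4))
star  <- make_siemens_star(g, n_spokes = 36, r_outer = 5)
drift <- sample_drift(ill, magnitude = pi, seed = 101)

ds  <- simulate_dataset(star, pupil_in, pupil_out, drift, ill)
fit <- run_class(ds, max_iter = 15, rel_tol = 1e-6)
fit$state
#> <sa_correction> 1201 input / 1201 output phases, 5 iterations (converged)
#>   total SA intensity: 2.5127e+06 -> 1.58114e+10
```

The total SA intensity grows ~6300-fold as the corrections converge. The
recovered maps match the generator's ground truth to a fraction of a
milliradian (circular RMS, gauge removed):

```r
n <- g$n
ill_lin <- (ill$q + n/2) * n + (ill$p + n/2) + 1
out_lin <- (ds$out_points$q + n/2) * n + (ds$out_points$p + n/2) + 1
circular_rms_phase_error(fit$state$theta_i,
                         pupil_in$phase[ill_lin] + drift$g, ill)
#> [1] 8.725472e-05        # theta_i -> phi_i + g
circular_rms_phase_error(fit$state$theta_o,
                         pupil_out$phase[out_lin], ds$out_points)
#> [1] 3.044611e-05        # theta_o -> phi_o
diffraction_limit(785, 1.2, 1.2)
#> [1] 327.0833            # nm — the two-sided resolution limit
```

`sa_image(fit$sa, normalize = "weights")` returns the corrected complex
image (`plot(fit$sa)` shows the spectrum); on the corrected reconstruction
`siemens_resolution()` reads a finest resolved period within one frequency
bin of the 327 nm limit, while the uncorrected reconstruction resolves
nothing. For the drift/input separation, simulate the second geometry with
`simulate_conjugate_dataset()`, solve it the same way, and call
`separate_input()` on the two output corrections.

A file-based pipeline with YAML configs mirrors the R API
(`cli_simulate()`, `cli_correct()`, `cli_separate()`, `cli_report()`,
`cli_demodulate()`); a thin executable wrapper ships at
`inst/cli/saclass`, and `inst/extdata/example_run.yaml` is a complete
configuration.

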