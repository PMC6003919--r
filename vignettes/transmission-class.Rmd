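---
title: "Transmission-mode CLASS: model, algorithm, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission-mode CLASS: model, algorithm, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saclass)
```

## The measurement and its distortions

High-NA condenser lenses offer millimetre-scale working distances that
ordinary high-NA objectives cannot, at the price of severe pupil aberration,
especially beyond ~0.8 NA. In a transmission-mode off-axis holographic
microscope built from two such condensers, a plane wave of transverse
wavevector $k^i$ illuminates a thin sample and the transmitted field is
recorded coherently for every $k^i$ inside the illumination aperture. In
frequency space the measurement of a sample with object spectrum
$O(\Delta k)$ is

$$E_o(k^o;\,k^i) \;=\; P_o^a(k^o)\, O(k^o - k^i)\, P_i^a(k^i)\,
  e^{i g(k^i)},$$

where $P^a_{i,o} = \exp(i\varphi_{i,o})$ are unit-amplitude pupil transfer
functions on the closed disks $|k| \le \mathrm{NA}\,k_0$
($k_0 = 2\pi/\lambda$), and $g(k^i)$ is an uncontrolled global phase per
acquisition caused by path-length drift between the sample and reference
arms. Summing all measurements at equal momentum difference
$\Delta k = k^o - k^i$ gives the synthetic-aperture (SA) spectrum

$$E_{SA}(\Delta k) = \sum_{k^i} E_o(k^i + \Delta k;\,k^i)
  \;=\; O(\Delta k) \sum_{k^i} P_o^a(k^i{+}\Delta k)\,P_i^a(k^i)\,
  e^{i g(k^i)},$$

whose support reaches $(\mathrm{NA}_{ill} + \mathrm{NA}_{col})\,k_0$: the
two-sided diffraction limit $\Delta = \lambda/(\mathrm{NA}_{ill} +
\mathrm{NA}_{col})$. With aberration or drift the cross-correlation factor
de-phases, so the total SA intensity $\sum_{\Delta k}|E_{SA}|^2$ can only be
smaller than in the ideal system — the quantity the solver maximizes.

## The iterative correction (CLASS)

The solver searches for an input correction $\theta_i(k^i)$ and an output
correction $\theta_o(k^o)$, applied as $e^{-i\theta}$, that maximize the
total SA intensity. Each *input half-step* correlates every
single-illumination spectrum against the aggregate SA spectrum and advances
$\theta_i(k^i)$ by the phase of that scalar product; the *output half-step*
is the same rule with illumination and detection exchanged, which is
realized by numerically phase-conjugating the data (conjugate every entry
of the transmission matrix and transpose it — `phase_conjugate()`). Because
conjugation re-attaches the drift factor to the detection index, the
recovered $\theta_o$ is decoupled from $g$; the accumulated corrections
converge to $\sum_n \theta_i^{(n)} \to \varphi_i + g$ and
$\sum_n \theta_o^{(n)} \to \varphi_o$. At the joint optimum every term in
every $\Delta k$ bin is phase-aligned, which bounds each bin by its
aberration-free value — so ground truth (up to gauge, below) is the global
maximizer on noise-free data.

Iteration runs input-first, then output, per full iteration (the order is
configurable), with the total intensity recorded after every half-step and
a relative-change stopping rule (`rel_tol`, default $10^{-6}$ over one full
iteration; `max_iter` default 15, convergence typically well before that).

### Correlation weighting

The textbook correlation target is the raw aggregate
$\sum_{\Delta k} \tilde E\,\overline{E_{SA}}$, whose per-bin weight is the
object's spectral power $|O(\Delta k)|^2$ times the pair count. On a
transparent-background amplitude target the DC bin then carries ~3/4 of the
vote, and the DC bin constrains only the *sum* $\theta_i + \theta_o$, not
the split between the two pupils; the input/output common-mode error decays
at the off-DC weight share, which we measured at about 1 % per iteration on
the standard scenario below — far too slow. The package therefore
normalizes each $\Delta k$ bin of $E_{SA}$ to unit modulus before the dot
product (`weighting = "consensus"`, the default). The fixed points are
unchanged — the condition is still that every pairwise dot product is real
— but each bin gets an equal vote, and on noise-free data every nonzero bin
carries exact phase information, giving a uniform geometric convergence
rate (machine-precision recovery within ~5 iterations on the standard
scenario, monotone intensity trace to within $4\times10^{-15}$ relative).
The raw form is available as `weighting = "intensity"`; it is the better
choice if bins are noisy, since consensus weighting gives meaningless
near-empty bins the same vote as strong ones. A per-pair (rather than
aggregate) correlation variant is noted in the literature; it is not built.

### Gauge freedoms

Two freedoms leave the objective invariant: a piston per map, and the
paired tilt $(+a\cdot k$ on $\theta_i$, $-a\cdot k$ on $\theta_o)$, which
is a rigid translation of the reconstructed image. `remove_gauge()`
(applied by `run_class()`) zeroes both maps at the lattice origin and
removes the shared tilt estimated by least squares,
$\hat a = (\mathrm{tilt}(\theta_i) - \mathrm{tilt}(\theta_o))/2$. One
caveat: because half-step increments are wrapped phases, accumulated maps
can carry $2\pi$-jump fields when the true aberration exceeds $\pi$, which
makes *absolute* tilt estimation on the raw maps unreliable. All recovery
metrics therefore quotient gauge on the **wrapped difference** between
estimate and truth (`circular_rms_phase_error()` /
`align_phase_residual()`: circular-mean piston, then an iterated
least-squares tilt fit on the wrapped, small residual), and reconstructed
images are registered by cross-correlation (`estimate_image_shift()`)
before quantitative reading.

## Separating the input aberration from the drift

$\theta_i$ converges to $\varphi_i + g$ — aberration and drift are
inseparable from one dataset. A second acquisition with the test target at
the conjugate image plane before the input condenser sees no input-side
aberration and the *product* pupil $P_o^a P_i^a$ on the output side, so its
output correction $\theta_o'$ converges to $\varphi_o + \varphi_i$.
`separate_input()` returns the wrapped difference $\theta_o' - \theta_o
\to \varphi_i$, independent of both drift realizations. The package
simulates this geometry with `simulate_conjugate_dataset()` and tags every
dataset with its `configuration`, which the file-level pipeline
(`cli_separate()`) checks before subtracting.

## The synthetic data generator

The generator is first-class, seeded, and defines the study conditions:

* **Objects.** A binary Siemens star (`make_siemens_star()`: equal
  opaque/transparent sectors inside `r_outer`, transparent outside) reads
  resolution as the finest resolved azimuthal period; a unit-amplitude
  Gaussian-bump phase object (`make_phase_blobs()`) emulates transparent
  cells with granular internal structure; `make_point_object()` gives the
  flat-spectrum limiting case.
* **Aberrations.** `make_condenser_aberration()` builds even-power radial
  polynomials in the normalized pupil radius,
  $\sum_j c_j\,\rho^{2j}$, piston-free by construction, matching the
  spherically symmetric, edge-steep phase maps characteristic of condenser
  pupils; low-order astigmatism/coma terms can be added. A Zernike basis is
  deliberately not the canonical form — the radial parameterization keeps
  ground truth trivially serializable.
* **Drift.** I.i.d. uniform phases in $[-m, m]$ per illumination
  (`sample_drift()`). The experimental drift magnitude is not something the
  package can know; the default $m = \pi$ (total phase scrambling) is the
  least-informative bounded choice and the hardest case for the solver,
  which must not depend on the drift distribution.
* **Holograms.** `synthesize_hologram()` renders camera-like off-axis
  interferograms $|E_S + E_R|^2$ with a lattice carrier (so demodulation is
  an exact index shift); optional Poisson shot noise at a configurable full
  well, off by default — simulated spectra are noise-free unless
  holograms are synthesized and demodulated.

What the generator does **not** emulate: partial coherence, multiple
scattering, defocus between planes, vectorial pupils, camera readout
artifacts. Passing tests therefore demonstrate the algorithmic claims
(recovery, monotonicity, drift decoupling, resolution closure) on single-
scattering data, not robustness to those physical effects.

## Numerical conventions and edge cases

* Frequency lattice: integer indices $(p, q) \in [-n/2, n/2)$, physical
  $k = (p,q)\,2\pi/L$; one convention shared by every module so the
  $\Delta k = k^o - k^i$ arithmetic is exact. Transforms are unitary.
* Cutoffs are closed disks $|k| \le \mathrm{NA}\,k_0$ (boundary included),
  for pupils, illumination enumeration, and the demodulation low-pass
  alike. Constructors reject apertures beyond Nyquist instead of silently
  truncating, and `simulate_dataset()` additionally requires
  $(\mathrm{NA}_{ill}{+}\mathrm{NA}_{col})k_0$ within Nyquist so the
  momentum-difference lattice cannot wrap. For a 50 µm field at 1.2 NA the
  closed-disk mode count at $\lambda = 785$ nm is what
  `enumerate_illuminations()` returns (deterministic, row-major by
  $(q,p)$); no attempt is made to match any particular instrument's count.
* The off-axis separation condition ($|k^R| > 3\times$ band radius, and
  non-overlap of the mirror copy) is an error in
  `demodulation_settings()` and a warning at synthesis time. The low-pass
  filter edge is hard (apodization is not applied), keeping the round trip
  exact to machine precision within the passband.
* Exactly-zero correlations in a half-step yield a zero increment and a
  warning rather than an undefined `arg`.
* Single-pair $\Delta k$ bins participate unweighted in $E_{SA}$ (the sum
  is the plain unweighted sum); weight normalization exists only as an
  *imaging* option: `sa_image(normalize = "weights")` divides each bin by
  its pair count, equalizing the transfer function to an ideal coherent
  aperture of radius $(\mathrm{NA}_{ill}{+}\mathrm{NA}_{col})k_0$.
* The intensity of a field band-limited at $K$ has spectral content to
  $2K$; `sa_image(oversample = 4)` renders on a zero-padded lattice so that
  quantitative contrast analysis of $|E|^2$ is alias-free.
* `siemens_resolution()` sweeps circles inward and stops at the first
  radius whose spoke-frequency Michelson contrast drops below threshold
  (contiguity: isolated speckle passes deeper in never count), excluding
  periods under two pixels. The default threshold is *aperture-calibrated*:
  half the resolved-zone plateau contrast, because an ideal filter
  transmits exactly half the amplitude at its cutoff — a fixed absolute
  threshold (the exposed alternative) reads one PSF width into the filter
  tail instead.
* `airy_fit()` fits $s\,[2 J_1(x)/x]^2$ over the centre through the first
  dark ring only (ring-weighting further out is ambiguous); FWHM uses
  sub-pixel quadratic peak localization and linear interpolation of the
  half-maximum crossings.

## Problem sizes

The reference ("standard") scenario used by the tests and by
`scripts/acceptance.R`: 12.8 µm field, $128^2$ pixels, $\lambda = 785$ nm,
both pupils at NA 1.2 with radial aberrations summing to 6 rad at the pupil
edge, a 36-spoke star of 5 µm radius, drift uniform in $\pm\pi$ — about
1200 illuminations and a $1201 \times 1201$ complex transmission matrix,
solved in well under a minute. Smaller 32-pixel scenes cover properties
needing many repetitions or full convergence (the drift-decoupling bound is
a fixed-point property, so it is checked on a small grid run to numerical
convergence rather than within the 15-iteration budget).

## Known limitations

* Amplitude (apodization) of the pupils is assumed unity and is not
  estimated; samples must be dominated by single scattering.
* The one-step increments are not exact closed forms: with closed-disk
  supports the per-bin contributor sets vary with $\Delta k$, so a single
  half-step carries a second-order error and exact recovery is a
  fixed-point (iterated) property.
* True aberrations whose genuine tilt component matters cannot be
  distinguished from the translation gauge; all reported maps are
  tilt-quotiented.
* Datasets are stored dense (output support × illuminations); memory grows
  as the fourth power of the linear aperture-to-field ratio. The 19.6k-mode
  configuration of a 50 µm field at 1.2 NA would need a ~6 GB complex
  matrix — out of reach of this in-memory layout.
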