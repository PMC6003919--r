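Package: saclass
Title: Computational Aberration Correction for Synthetic-Aperture Holographic Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transmission-mode closed-loop accumulation of single
    scattering (CLASS) microscopy. Simulates angle-scanned coherent
    transmission datasets through two aberrated large-aperture lenses,
    demodulates off-axis holograms with the 2D Hilbert transform, estimates
    and corrects input- and output-pupil phase aberrations (entangled with
    per-illumination phase drift) by iteratively maximizing the total
    intensity of the synthetic-aperture spectrum, separates the pure input
    aberration with a second measurement configuration, and quantifies the
    result with PSF, Strehl, FWHM, Airy-fit and Siemens-star resolution
    metrics.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
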