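Package: mrsfit
Title: Time-Domain AMARES Fitting of in Vivo Magnetic Resonance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies metabolites in magnetic resonance spectroscopy (MRS)
    free-induction decays by time-domain fitting of sums of exponentially
    damped sinusoids under flexible prior knowledge (the AMARES approach):
    declarative per-peak bounds, starting values, multiplet splittings,
    parameter grouping and offsets are compiled into an affine constraint
    map, amplitudes and phases are initialised by linear least squares, and
    the free parameters are refined by bounded nonlinear least squares.
    Parameter uncertainties are reported as Cramer-Rao lower bounds from the
    constrained Fisher information, including delta-method bounds for
    arbitrary derived expressions with persistent compiled-gradient caching.
    Includes a Siemens DICOM spectroscopy importer (CSA1/CSA2 private
    headers, DICOMDIR, cached directory scanning), voxel geometry mapping,
    a plain-text fixture format, a synthetic FID and CSI-phantom generator,
    and batch fitting of chemical shift imaging grids with tabular results
    and static fit and amplitude-map figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    patchwork,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
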