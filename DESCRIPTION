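Package: cvimp
Title: Cerebrovascular Impedance Indices from Diffuse Optical and Pressure Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies a cerebrovascular impedance index from co-localized
    pulsatile cerebral blood flow (diffuse correlation spectroscopy) and blood
    volume (near-infrared spectroscopy) recordings at the cardiac fundamental
    and first harmonic frequencies, and builds impedance-versus-CPP and Lassen
    autoregulation curves that locate the lower and upper limits of cerebral
    autoregulation. Includes the full processing chain (stream alignment,
    high-pass isolation of cardiac pulsatility, windowed FFT spectra,
    SNR-based window rejection, CPP binning, cohort averaging, piecewise-linear
    limit estimation), an SNR-weighted correlation-diffusion fit for the DCS
    flow index, modified Beer-Lambert chromophore unmixing, and a synthetic
    recording generator with known ground-truth impedance for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
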