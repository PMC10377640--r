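Package: rpoxim
Title: Monte Carlo Photon Transport and PPG Analysis for Ring-Type Pulse Oximeters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional weighted-photon Monte Carlo simulation of light
    transport in a layered human-finger model for ring-type pulse oximeter (RPO)
    design. Builds a cylindrical finger with a layered tissue map (epidermis,
    four dermis sublayers, subcutaneous fat, bone, two digital arteries), mixes
    chromophore absorption spectra by volume fraction as a function of
    wavelength, oxygen saturation and cardiac phase, and transports photon
    packets with Henyey-Greenstein scattering and Russian roulette between an
    LED source and a photodetector placed along the ring rim, with either an
    absorbing or a mirror-coated surround. A derived-quantity pipeline computes
    dc/ac detected intensity, perfusion index, R ratio, the SpO2 calibration
    curve, reliability limits and the optimal detector angle, plus a
    photoplethysmography waveform-analysis chain (zero-phase bandpass, envelope
    dc/ac extraction, band-ratio SNR) with a synthetic two-wavelength PPG
    generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
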