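Package: orbiso
Title: Ion-Count Based Isotope Ratio Processing for Orbitrap Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Orbiso", "Developers", email = "orbiso@example.org", role = c("aut", "cre"))
Description: Processes high-resolution Orbitrap mass spectrometry acquisitions
    into carbon isotope ratios and delta-13C values. Converts per-peak
    signal-to-noise into theoretical ion counts with a resolution correction,
    computes per-scan and count-weighted aggregate 13C/12C isotopologue
    ratios, applies retention-time culling and robust outlier rejection,
    corrects instrumental drift with standard-block regression over a
    bracketed standard/sample sequence, and reports shot-noise and
    AGC-regulation diagnostics including in-window contaminant detection.
    Ships a seeded forward simulator of AGC-regulated acquisitions (Poisson
    ion statistics, electrospray suppression, linear drift, space-charge
    ratio bias) so every processing stage is testable without instrument
    files, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
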