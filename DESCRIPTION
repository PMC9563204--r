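Package: structms
Title: Structural Mass Spectrometry Validation of Protein Complex Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating candidate structures of protein complexes
    against solution-phase mass spectrometry. Implements orientation-averaged
    projection-approximation collision cross-sections (CCS) from atomic
    coordinates with empirical scaling, traveling-wave ion-mobility
    calibration against reference CCS values, native mass spectrum
    deconvolution into neutral masses and stoichiometries, titration
    analysis, peptide-level hydrogen-deuterium exchange (HDX) uptake
    kinetics with one- and two-phase association fits, and CCS-based
    discrimination between candidate complex architectures. A synthetic-data
    module generates spectra, arrival-time distributions, uptake tables and
    toy geometries with recorded ground truth so every stage is testable
    without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
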