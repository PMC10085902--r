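Package: diatomLD
Title: Quantitative SEM Diatom Testing for Forensic Drowning Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantitative scanning
    electron microscopy (SEM) diatom testing on circular filtration
    membranes. Simulates homogeneous and clustered diatom deposition on a
    membrane disc, builds transectial and scatter field-of-view acquisition
    plans, extrapolates whole-membrane diatom abundance from sampled fields
    with exact square-in-disc area clipping, fits logarithmic
    accuracy-versus-image-count models to derive minimum image requirements,
    and computes the L/D diagnostic ratio (diatoms per gram of lung tissue
    over diatoms per ml of drowning medium) with diagnostic classification,
    tissue-weight replicability statistics, peripheral-tissue categorisation
    and acid-digestion volume recommendations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
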