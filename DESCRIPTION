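Package: nephroflow
Title: Single-Nephron GFR and Glomerular Morphometry from Intravital
    Multiphoton Imaging
Version: 0.1.0
Authors@R:
    person("Nephroflow", "Developers", email = "nephroflow@example.org",
           role = c("aut", "cre"))
Description: Quantifies single-nephron glomerular filtration rate (snGFR)
    from the transit of a freely filtered fluorescent tracer along the
    proximal tubule in intravital two-photon time series, and performs 3D
    morphometry of afferent/efferent arterioles (mean diameter by maximal
    inscribed sphere) and glomerular capillary tufts (volume) from z-stacks.
    Includes a synthetic multiphoton image generator with analytic ground
    truth for validation, semi-automatic tubule tracing from user seed
    points, paired before/after treatment statistics with Sidak-adjusted
    multiple comparisons, and a batch pipeline with TIFF/YAML/JSON/CSV
    interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
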