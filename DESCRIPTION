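Package: conflictlba
Title: Approach-Avoid Conflict Behavior, Linear Ballistic Accumulator
    Modeling, and Fiber Photometry on the Linear Track
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for approach-avoid decision-making under
    motivational conflict on a linear track. Extracts behavioral
    microstructure (pauses, approach/avoid outcomes, spatial decision
    zones) from tracking traces, fits the linear ballistic accumulator
    (LBA) race model to pause-resolved choices by Hamiltonian Monte
    Carlo with standard convergence diagnostics, computes
    isosbestic-corrected fiber-photometry dF/F with bootstrap
    significance of peri-event transients, and links calcium signals to
    decision parameters through per-subject correlation and regression.
    Includes a ground-truth-labeled synthetic cohort generator for
    validation, since the behaviors the pipeline targets are defined
    statistically rather than by deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
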