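Package: mpnrux
Title: Stem and Progenitor Cell Dynamics in Myeloproliferative Neoplasms
    under Ruxolitinib
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compartmental ODE model of haematopoiesis in JAK2 V617F-driven
    myeloproliferative neoplasms: healthy and malignant stem, progenitor and
    mature blood cells coupled through stem-cell niche crowding, cellular
    debris and cytokine feedback. Ruxolitinib therapy enters as dose-dependent
    increases of the malignant stem-cell cytokine half-saturation constant and
    the malignant progenitor death rate. Provides steady-state enumeration
    with local stability analysis, treatment scenario simulation, basin-of-
    attraction thresholds, local parameter sensitivity ranking, per-patient
    nonlinear least-squares fitting of treatment-response parameters to JAK2
    variant-allele-frequency time series with sampling-based approximate
    confidence bands, and a synthetic-patient cohort generator for method
    validation.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
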