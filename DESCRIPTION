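Package: erythrosim
Title: Individualized Age-Structured Modeling of Erythropoiesis in
    Hemodialysis Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates red blood cell production as a five-class
    age-structured population model (BFU-E, CFU-E, erythroblasts, marrow
    reticulocytes, circulating erythrocytes) driven by endogenous
    erythropoietin and bolus doses of an erythropoiesis-stimulating agent.
    Maps simulated cell counts to pre- and post-dialysis hemoglobin through
    Nadler blood volumes, estimates five patient-specific parameters (red
    cell lifespan, endogenous EPO level, ESA half-life, and the slopes of
    the CFU-E apoptosis and reticulocyte maturation-velocity responses)
    from per-treatment hemoglobin series by multi-start Nelder-Mead on a
    least-squares cost, and evaluates adaptation fits and frozen-parameter
    forecasts with the mean absolute percentage error and the Kantorovich
    (Wasserstein-1) distance. Includes a synthetic hemodialysis cohort
    generator so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
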