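Package: mpgrepair
Title: Glycosylase Turnover Kinetics and In-Cell Base Excision Repair Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of pre-steady-state kinetics for the DNA
    glycosylase MPG (N-methylpurine-DNA glycosylase) and of qPCR-based in-cell
    DNA repair assays. Provides synthetic-data generators (reaction-mechanism
    ODE simulation, single-turnover and burst progress curves, active-site
    titration series, in-cell repair time courses, Ct tables, mixing standards,
    SPR sensorgrams), nonlinear least-squares fitting of single-turnover and
    burst equations with product-dissociation rate and active-fraction
    estimation, repair half-life estimation with assay-linearity validation,
    global 1:1 Langmuir binding fits, hotspot versus non-hotspot group
    comparisons, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
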