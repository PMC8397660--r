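Package: neutroqsp
Title: Quantitative Systems Pharmacology Simulator for Maturation-Block Neutropenia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates drug-induced neutropenia caused by a block of
    late-stage neutrophil maturation, the mechanism of cereblon E3 ligase
    modulator (CELMoD) compounds such as avadomide.  Couples a
    six-compartment neutrophil life-cycle ODE model (proliferation, three
    maturation transit stages, bone-marrow reservoir, circulation) with a
    two-compartment oral PK model and an inhibitory Emax PD effect on the
    transit-2 to transit-3 maturation flux.  Provides the homeostatic
    parameter cascade that back-calculates all transit rates from baseline
    neutrophil count, per-patient fitting of longitudinal ANC profiles by
    Nelder-Mead direct search, virtual-patient cohort generation by kernel
    density estimation of fitted parameter distributions, virtual
    dose/schedule trial screening with CTCAE grade 3/4 toxicity endpoints,
    two-sample Kolmogorov-Smirnov cohort validation, and Monte Carlo
    (Latin hypercube / PRCC) global sensitivity ranking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    lhs,
    nortest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
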