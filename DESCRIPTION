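Package: exoflux
Title: Cellular Pharmacokinetics and Pharmacodynamics of Exosome-Mediated Drug Efflux
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic modeling of exosome-mediated efflux of paclitaxel from
    tumor cells. Provides a cellular pharmacokinetic ODE model of drug pools in
    medium, cytosol, tubulin, pre-exosome vesicles and extracellular exosomes,
    with fractional inhibition of vesicle sorting (alpha) and exosome release
    (beta); a coupled growth/kill pharmacodynamic model of donor-cell
    cytotoxicity; weighted least-squares estimation of the inhibition fractions
    with BIC model selection and hold-out validation; curve-shift and
    uncertainty-envelope drug-interactivity analysis with the extent-of-
    interactivity statistic; and seeded synthetic-data generators emulating the
    study design so the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
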