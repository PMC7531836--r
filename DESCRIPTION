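Package: altpathsim
Title: Simulation of the Alternative Complement Pathway and
    Complement-Mediated Hemolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistic ordinary-differential-equation model of the
    alternative complement pathway (AP), from spontaneous C3 tick-over to
    membrane-attack-complex (MAC) formation on erythrocyte surfaces.  The
    model couples fluid-phase and surface biochemistry to MAC-mediated
    hemolysis through a Hill dose-response, to in-vivo protein and
    erythrocyte turnover, to the hematological biomarkers hemoglobin,
    hematocrit and lactate dehydrogenase, and to the pharmacokinetics and
    target engagement of the anti-C5 antibody eculizumab.  Includes
    declarative scenario configurations for standard hemolytic assays,
    regulator-knockout screens and paroxysmal nocturnal hemoglobinuria
    (PNH), a sum-of-squared-residuals calibration engine with
    coordinate-descent optimization, local sensitivity analysis, seeded
    synthetic-data generators, SBML export and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    xml2,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
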