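Package: sersmcr
Title: SERS Antibiotic Screening with MCR-ALS Spectral Unmixing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening veterinary antibiotic residues (enrofloxacin,
    oxytetracycline, neomycin) from surface-enhanced Raman spectra of water
    and pig urine samples. Provides a seeded synthetic spectrum generator with
    configurable fluorescence and matrix models, asymmetric-least-squares
    baseline correction, a multivariate curve resolution solver by alternating
    non-negative least squares (MCR-ALS) with reference-guided initialization
    and cosine component assignment, characteristic-peak calling,
    univariate and unmixing-based limit-of-detection determination, and
    maximum-residue-limit screening reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
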