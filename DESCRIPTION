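Package: cocun
Title: Solution-State Characterization of the CoCUN Ubiquitin-Binding Domain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analyses for the solution-state characterization of
    the CoCUN domain, the C-terminal ubiquitin-binding domain of N4BP1:
    chemical-shift-index secondary-structure assignment from backbone
    chemical-shift tables, chemical-shift-perturbation (CSP) interface
    mapping from HSQC titrations under two-state fast exchange, one-site
    isothermal titration calorimetry (ITC) simulation and fitting, circular
    dichroism (CD) difference spectroscopy with a transparent helix-content
    estimator, pairwise alignment and ubiquitin-binding-domain motif
    scanning, and seeded synthetic-data generators that emulate each
    experiment so the whole pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
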