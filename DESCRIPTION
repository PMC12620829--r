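Package: adasim
Title: Quantitative Systems Pharmacology Simulation of Anti-Drug Antibody
    Formation and Its Impact on Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Couples a minimal physiologically based pharmacokinetic model
    of a protein therapeutic with a mechanistic ordinary differential
    equation model of the humoral immune response to simulate anti-drug
    antibody (ADA) formation in virtual clinical trials. T-cell activation
    is driven by MHC class II elution-rank scores of selected epitopes
    restricted to each virtual subject's sampled HLA class II genotype;
    methotrexate co-medication inhibits T-cell proliferation through an
    inhibitory Emax model. Trials classify ADA positivity against an assay
    threshold, test exposure impact with a Wilcoxon rank-sum comparison,
    and compute the molar ADA to drug concentration ratio risk metric,
    including dose adjustment scans and calibration of the
    antigen-presentation half-activation constant against observed
    incidences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
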