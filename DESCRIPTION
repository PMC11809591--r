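Package: poslabel
Title: Carbon-Positional 13C Enrichment Analysis from GC-MS In-Source Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for carbon-positional stable-isotope labeling analysis of
    primary metabolites measured by GC-(TOF)MS. Corrects measured isotopologue
    distributions for natural isotope abundance of all elements and for tracer
    isotopic purity, computes fractional 13C enrichment of paired in-source
    fragments, combines them into positional enrichment at the 1-C carboxyl
    position of 3-phosphoglycerate, converts enrichments to molar 13C
    concentrations via calibration-based quantification, and fits labeling
    time courses with logistic and exponential models to estimate carbon
    assimilation rates. Includes glucose-to-3PGA carbon-fate maps for the
    Embden-Meyerhof-Parnas and oxidative pentose-phosphate pathways, the
    RUBISCO carboxylation mapping, and a seeded synthetic-data generator that
    emulates dynamic 13CO2 pulse-labeling experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
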