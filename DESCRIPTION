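Package: phosbif
Title: Phosphite and Phosphate in Early Precambrian Seawater from Banded
    Iron Formations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reconstructs dissolved phosphite (P(III)) and phosphate (P(V))
    concentrations in Neoarchean-Paleoproterozoic surface seawater from the
    chemistry of banded iron formations (BIFs).  Fits linear sorption
    isotherms to hydrous-ferric-oxide co-precipitation experiments to obtain
    adsorption coefficients (K_ads), quantifies phosphorus species in
    EDTA-NaOH rock extracts from ion-chromatography ICP-MS chromatograms,
    brackets seawater concentrations under scenario-based assumptions about
    extraction efficiency and metamorphic phosphite production, and analyses
    phosphite-dehydrogenase gene trees (monophyly, Fitch parsimony with
    constrained root states, minimal-ancestor-deviation rooting) to compare
    assimilatory and dissimilatory phosphite oxidation.  Seeded synthetic-data
    generators emulate every input so the full chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phytools,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
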