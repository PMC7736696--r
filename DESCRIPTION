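Package: glycoflow
Title: MS1 Feature-Graph Glycopeptide Identification and Label-Free Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semiautomated glycoproteomics workflow for enriched
    glycoproteins: deisotoping and decharging of centroided MS1 scans into
    neutral-mass features, mass-difference/retention-time graph clustering of
    glycopeptide features with anchor-based glycan composition propagation and
    illogical-composition filtering, conversion of cluster output to targeted
    analyte lists, and label-free relative quantification from summed MS1
    spectra with isotopic-pattern, mass-accuracy and signal-to-noise quality
    control. Includes exact-mass and isotope-pattern chemistry for peptides and
    N-glycans, and a seeded synthetic LC-MS data generator emulating tryptic
    IgG/IgA glycopeptide clusters with formylation and cysteine-oxidation
    confounders.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    mzR,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
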