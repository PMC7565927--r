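Package: egfofuc
Title: O-Fucosylation Site Analysis for EGF-Like Domain Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein O-fucosylation on EGF-like domains
    (EGF-LDs), built around the WIF1 family of Wnt inhibitors. Detects EGF-LDs
    by their six-cysteine framework, scans for the C2XXXX(S/T)C3 O-fucosylation
    consensus, scores POFUT1 substrate compatibility from sequence-level rules,
    aligns ortholog domains on their cysteine anchors, builds species-by-domain
    site presence matrices, reconstructs gains and losses of glycosylation
    sites over a species tree by Fitch parsimony, performs in silico protease
    digestion (trypsin, thermolysin and co-digestion with missed cleavages),
    computes glycopeptide monoisotopic masses and MRM transition lists, and
    quantifies site occupancy from transition peak areas. Includes a seeded
    synthetic-data generator emulating ortholog families and MRM peak tables
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
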