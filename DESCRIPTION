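Package: mipscreen
Title: Identification of Microtubule Inner Proteins from Quantitative
    Proteomics, Sequence Signatures and Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative screening toolkit for assigning unidentified
    cryo-EM densities of the ciliary doublet microtubule to candidate
    proteins. Implements the Rough Stoichiometric Peptide Abundance
    (RSPA) copy-number proxy from label-free spectral counts,
    wild-type versus knockout differential classification (completely
    missing and fold-reduced categories), density-signature regular
    expression searches over a proteome with length windows and trace
    directions, a multi-criteria candidate screen combining
    stoichiometry, size, cross-species conservation and localization
    evidence, Pearson tissue co-expression with exclusion re-analysis,
    and seeded synthetic-data generators that emit ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
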