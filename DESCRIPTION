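Package: coexminer
Title: Frequent Itemset and Association Rule Mining of Occupational
    Chemical Coexposures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize coexposure to multiple airborne chemical
    agents in occupational exposure databases. Personal air-measurement
    records are filtered by detection status and sample-count rules, grouped
    into work situations (unique combinations of industrial sector,
    occupation, task and calendar year), and reduced to a transaction
    database of detected agents. A depth-first Eclat-style miner extracts
    frequent agent itemsets with exact work-situation counts, and an
    association-rule generator scores antecedent/consequent rules with
    support, confidence and lift, including the complementary-rule
    confidence. Carcinogen-restricted, sector- and task-stratified
    subanalyses and pairwise co-occurrence matrices are provided, together
    with a synthetic corpus generator with analytically known mixture
    prevalences for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'coexminer-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'fim.R'
    'pipeline.R'
    'records.R'
    'rules.R'
    'subanalyses.R'
    'synth.R'
    'transactions.R'
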