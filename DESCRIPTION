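Package: rnrspec
Title: Phosphate Specificity Analysis for Class II Ribonucleotide Reductases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict and analyse the phosphate specificity (NDP
    versus NTP reduction) of class II ribonucleotide reductases (NrdJ)
    from protein sequence. Locates the apical loop of the phosphate-binding
    site by pairwise anchoring to an annotated reference or by designated
    alignment columns, classifies the extracted motif against a curated
    motif lexicon, builds sequence-logo matrices, maps specificity states
    onto phylogenies with Fitch parsimony and monophyly tests, summarises
    per-genome co-occurrence of differently specific NrdJ copies, and fits
    Michaelis-Menten and substrate-surplus-inhibition kinetic models to
    enzyme assay data. Includes seeded generators for synthetic motif-planted
    protein families, multi-copy genomes, trees with evolved motif states,
    and noisy saturation-kinetics datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    yaml
Config/testthat/edition: 3
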