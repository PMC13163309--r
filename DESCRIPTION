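Package: netprio
Title: Network-Guided Target and Metabolite Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for network-guided drug-target and metabolite
    prioritization in transcriptomic and metabolomic studies of
    chemotherapy-induced stress adaptation. Provides seeded synthetic-data
    generators with planted ground truth, differential expression with an
    empirical-Bayes moderated t-test and Benjamini-Hochberg control,
    hypergeometric pathway over-representation analysis, a composite gene
    prioritization score combining enrichment significance, expression
    abundance and pathway-relevance weighting, protein-protein interaction
    network topology statistics, partial least squares discriminant analysis
    with variable-importance-in-projection metabolite selection, docking-table
    ligand ranking with multi-target profiles, and four-parameter-logistic
    dose-response (IC50) estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    jsonlite,
    fgsea,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
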