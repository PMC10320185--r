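Package: mirTEA
Title: miRNA-Centric Term Enrichment and Context-Aware Functional Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Target-based functional analysis of microRNAs. Builds combined
    target sets (union or n-way intersection) from miRNA-gene interaction
    tables, tests term/pathway overrepresentation with one-sided
    hypergeometric or bias-corrected Wallenius non-central hypergeometric
    statistics, and merges per-miRNA significance per term with Fisher's
    method. Enriched terms can be interrogated against expression contexts
    (cell types, tissues) by rank-based comparison of targeted versus
    non-targeted term components on percent-expressing log2 fold-changes.
    Includes term-centric discovery of candidate miRNA regulators,
    miRNA-centric analysis of pooled CRISPR knock-out selection screens
    (competitive rank-based testing against the opposite selection ranking),
    a seeded synthetic-fixture generator with plantable signal, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
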