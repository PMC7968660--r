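Package: steppenet
Title: Co-Occurrence Networks and Community Statistics for Soil Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds Spearman-threshold co-occurrence networks from OTU count
    tables and characterizes their topology (connectivity, average path
    distance, clustering, modularity), classifies node roles with
    within-module degree z-scores and participation coefficients, and
    compares empirical networks against Erdos-Renyi G(N,L) random nulls.
    Couples community composition to soil chemistry through diversity
    indices, one-way ANOVA with compact letter displays, and redundancy
    analysis with Monte Carlo permutation tests.  Includes a seeded
    synthetic-data generator with planted correlation modules and
    treatment-linked chemistry so the full pipeline can be exercised end to
    end without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
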