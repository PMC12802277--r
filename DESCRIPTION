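Package: nomvote
Title: Nomination-Voting Analysis of Dominant Taxon Emergence in
    Dilution-Cultivated Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how rare microbial taxa modulate which candidate
    taxon becomes the most abundant member of a community. Provides a
    synthetic generator for dilution-to-extinction cultivation experiments
    (heavy-tailed raw community, Poisson inoculation into 96-well plates,
    lottery or consumer-resource competition, per-well sequencing depth);
    the occurrence-analysis stage (read-depth filtering, dominant/rare
    labelling at 1% relative abundance, shared/appeared/disappeared
    partitions, dominance turnover classes, dominance-frequency groups,
    Top-N ranking, and the directed possibility-of-coexistence (POC)
    co-occurrence statistic with its five categories and four pairwise
    interaction types); and a consumer-resource ODE simulator implementing
    trait-based nomination, rare-background voting, and structured-rare
    interference experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    biomformat,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
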