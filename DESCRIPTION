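Package: lpsacyl
Title: LPS Acylation Profiling of Gut Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts lipopolysaccharide (LPS) structural capacity of gut
    bacterial species from pangenome gene-frequency tables using a rule set
    over the lipid A biosynthesis (lpx) genes, quantifies LPS biosynthesis
    genes and taxa with gene-count-per-million (GCPM), count-per-million
    (CPM) and centred-log-ratio (CLR) normalizations, computes hexa- to
    penta-acylated taxon and gene ratios, clusters samples into functional
    enterotypes with Jensen-Shannon divergence and partitioning around
    medoids, and runs the nonparametric association tests linking these
    features to anti-PD-1 immunotherapy response. Includes a synthetic
    cohort generator with planted effects so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
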