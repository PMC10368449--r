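Package: lpsmap
Title: Genotype-to-Phenotype Mapping of Bacterial LPS Mutants and Their Phages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping loss-of-function mutations in the Escherichia
    coli C lipopolysaccharide (LPS) core-oligosaccharide pathway to predicted
    LPS structures, and for confronting those predictions with the host
    ranges of evolved bacteriophages. Implements a dependency-graph
    truncation model of core-OS assembly, rough/deep-rough classification,
    mutation-table readers and summary statistics, consensus scoring of
    replicated spot assays, UPGMA clustering of binary infection matrices
    with dendrogram contiguity tests, Rand/adjusted-Rand partition
    concordance, combinatorial mining of phage mutation-capability
    association rules, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
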