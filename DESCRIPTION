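Package: cnvmech
Title: Mechanism Classification of Deletion CNVs from Chromatin Domain
    Architecture and Phenotype Ontology Similarity
Version: 0.1.0
Authors@R:
    person("cnvmech", "maintainers", email = "cnvmech@example.org",
           role = c("aut", "cre"))
Description: Classifies pathogenic deletion copy-number variants by their
    likely effect mechanism: disruption of a topological domain boundary
    that lets a tissue-specific enhancer act on a phenotypically relevant
    gene in the formerly insulated domain (enhancer adoption), classical
    gene-dosage effects through haploinsufficiency of deleted genes, a
    mixture of both, or neither.  Provides a rooted-DAG phenotype ontology
    with annotation propagation and corpus-specific information content,
    Resnik-style phenomatch and phenogram similarity scores between
    patient phenotype profiles and genes, tissue-specific DNase I
    hypersensitive site ranking from windowed count matrices via a
    regularised t-statistic, topological-domain boundary and adjacency
    geometry, permutation and random-placement null models, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
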