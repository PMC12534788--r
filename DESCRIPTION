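Package: pleioscope
Title: Cross-Domain Analysis of Gene Pleiotropy from Phenotype
    Ontologies and GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying and comparing the degree of gene
    pleiotropy across Mendelian-trait (phenotype ontology) and complex-trait
    (GWAS summary statistic) domains. Propagates ontology annotations to
    upper-level terms, computes per-gene degrees of pleiotropy and NP/ST/MP/HP
    pleiotropy classes, measures genotype-to-phenotype bipartite network
    modularity against degree-preserving permutation nulls, clusters traits on
    reconstituted phenotypic correlation, compares functional gene features
    across pleiotropy classes, aggregates per-SNP selection statistics (iHS,
    DRC150) to gene-level significance with length-matched resampling
    enrichment, and ranks non-redundant pathway enrichments. Ships a synthetic
    data generator with planted ground truth so every stage is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    data.table,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
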