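#!/usr/bin/env Rscript
# Gene-set analysis: hypergeometric over-representation of HP genes,
# greedy construction of a non-redundant pathway collection (strict > 25
# residual genes), and ranking sets by the minimum HP fraction across the
# ontology and GWAS datasets.

library(pleioscope)
source("analysis/00_paths.R")

sets <- read_gmt(inputs$gmt)
genes <- read_intervals(inputs$genes)
cls_onto <- read_features("results/classes_ontology.tsv")
cls_gwas <- read_features("results/classes_gwas.tsv")

hp <- cls_onto$gene[cls_onto$class == "HP"]
enr <- ora(hp, sets, genes$gene)
write_tsv(enr, "results/enrichment.tsv", "HP over-representation (hypergeometric + BH)")
message(sum(enr$p_adj < 0.05), " of ", nrow(enr),
        " sets enriched in HP genes at adjusted p < 0.05")

nr <- greedy_nonredundant(sets)
write_tsv(data.frame(order = seq_along(nr$selected), set = nr$selected),
          "results/nonredundant_sets.tsv", "greedy non-redundant selection")
message(length(nr$selected), " non-redundant sets cover ",
        round(100 * nr$coverage, 1), "% of the collection's genes")

# minimum HP fraction across both domains; the synthetic sets are small,
# so the per-dataset size filter is scaled to the collection
rank <- rank_min_hp_fraction(sets, list(ontology = cls_onto, gwas = cls_gwas),
                             min_set_size = 25L)
write_tsv(rank, "results/min_hp_fraction.tsv",
          "sets ranked by minimum HP fraction across datasets")
message("top sets by minimum HP fraction:")
print(head(rank, 5))
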