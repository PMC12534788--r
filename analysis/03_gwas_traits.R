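#!/usr/bin/env Rscript
# Complex-trait (GWAS) domain: filter traits by heritability z-score,
# clump lead SNPs, assign the closest gene, cluster traits on
# d = 1 - r_p (reconstituted phenotypic correlation), and derive the
# gene-by-trait-cluster matrix whose row sums are the GWAS degree of
# pleiotropy.

library(pleioscope)
source("analysis/00_paths.R")

genes <- read_intervals(inputs$genes)
manifest <- filter_traits(read_manifest(inputs$manifest))
message(nrow(manifest), " traits pass the heritability filter (Z > 2.32)")

stats <- lapply(manifest$trait, function(t) {
  read_sumstats(file.path(inputs$sumstats, paste0(t, ".tsv")), t)
})
names(stats) <- manifest$trait

leads <- do.call(rbind, lapply(stats, clump_lead_snps))
assigned <- closest_gene(leads, genes)
write_tsv(assigned, "results/lead_snps.tsv", "clumped lead SNPs with genes")
message(nrow(assigned), " lead SNPs across ", length(stats), " traits; ",
        sum(assigned$distance == 0), " fall inside their assigned gene")

dm <- trait_distance_matrix(stats)
clusters <- cluster_traits(dm$d)
message("trait clusters at cut 0.8: ", length(unique(clusters)))

m <- gene_cluster_matrix(assigned, clusters, dataset = "gwas")
deg <- gwas_degree(m, universe = genes$gene)
cls <- classify_pleiotropy(deg)
write_tsv(cls, "results/classes_gwas.tsv",
          paste0("GWAS classes, HP cutoff ", attr(cls, "cutoff")))
write_tsv(data.frame(gene = rownames(m), m, check.names = FALSE),
          "results/gene_cluster_matrix.tsv", "gene x trait-cluster incidence")
print(table(cls$class))
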