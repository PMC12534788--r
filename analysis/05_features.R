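#!/usr/bin/env Rscript
# Functional gene features across pleiotropy classes: expression breadth /
# median / max, PPI and GO counts, dosage sensitivity and constraint,
# compared with Wilcoxon-Mann-Whitney + BH; pLI > 0.9 proportions and
# FUSIL phenotype fractions with Wilson intervals.

library(pleioscope)
source("analysis/00_paths.R")

cls <- read_features("results/classes_ontology.tsv")
feats <- read_features(inputs$features)
expr_df <- read_features(inputs$expression)
expr <- as.matrix(expr_df[, -1, drop = FALSE]); rownames(expr) <- expr_df$gene

feats <- merge(feats, expression_summary(expr), by = "gene", all.x = TRUE)
cmp <- compare_numeric(
  feats, cls,
  feature_names = c("breadth", "median_tpm", "max_tpm", "ppi_count",
                    "go_bp_count", "pHaplo", "pTriplo", "LOEUF", "missense_z"),
  pairs = list(c("HP", "NP"), c("HP", "ST"), c("HP", "MP")))
write_tsv(cmp, "results/feature_comparisons.tsv",
          "Wilcoxon-Mann-Whitney with BH across all pairs x features")
sig <- cmp[cmp$p_adj < 0.001 & cmp$group2 == "NP", ]
message("HP vs NP features at adjusted p < 0.001: ",
        paste(sig$feature, collapse = ", "))

pli <- pli_proportions(feats, cls)
write_tsv(pli, "results/pli_proportions.tsv", "pLI > 0.9 proportion per class")
message("pLI > 0.9 proportion, HP vs NP: ",
        round(pli$prop[pli$class == "HP"], 3), " vs ",
        round(pli$prop[pli$class == "NP"], 3))

fus <- fusil_phenotype_fraction(cls, setNames(feats$fusil, feats$gene))
write_tsv(fus, "results/fusil_fractions.tsv",
          "fraction with any phenotype per FUSIL category")
print(fus)
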