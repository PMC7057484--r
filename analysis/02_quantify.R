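#!/usr/bin/env Rscript

# Quantification and replicate quality: FPKM from the simulated counts,
# the FPKM > 1 expression filter on genotype means, and pairwise Pearson
# correlations between biological replicates on log2(FPKM + 1).

library(triadbuffer)
library(readr)

counts <- read_counts("results/data/counts.tsv")
ann <- read_annotation("results/data/annotation.tsv", "tsv")
design <- read_design("results/data/design.tsv")

fpkm <- compute_fpkm(counts, ann)
gmeans <- genotype_mean_fpkm(fpkm, design)
expressed <- filter_expressed(fpkm, design, threshold = 1)
qc <- replicate_correlation(fpkm, design)

dir.create("results", showWarnings = FALSE)
write_tsv(tibble::tibble(gene_id = rownames(fpkm),
                         tibble::as_tibble(fpkm)), "results/fpkm.tsv")
write_tsv(tibble::tibble(gene_id = rownames(gmeans),
                         tibble::as_tibble(gmeans)), "results/fpkm_by_genotype.tsv")
write_tsv(tibble::tibble(gene_id = expressed), "results/expressed_genes.tsv")
write_tsv(qc, "results/replicate_qc.tsv")

message(sprintf("FPKM computed for %d genes; %d (%.1f%%) pass the >1 filter in >=1 genotype",
                nrow(fpkm), length(expressed), 100 * length(expressed) / nrow(fpkm)))
message(sprintf("replicate correlation on log2(FPKM+1): mean R^2 = %.3f (range %.3f-%.3f)",
                mean(qc$r_squared), min(qc$r_squared), max(qc$r_squared)))
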