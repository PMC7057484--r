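#!/usr/bin/env Rscript

# Differential transcription: the transparent NB Wald test (median-of-ratios
# normalization, trend-shrunk method-of-moments dispersions) applied to each
# aneuploid contrast, with BH-FDR 0.05 DTG calls and the chromosome-wise
# Down/Up distribution table. Monosomy is expected to produce mostly
# downregulated on-chromosome DTGs, trisomy mostly upregulated ones.

library(triadbuffer)
library(readr)

counts <- read_counts("results/data/counts.tsv")
ann <- read_annotation("results/data/annotation.tsv", "tsv")
design <- read_design("results/data/design.tsv")
fpkm <- compute_fpkm(counts, ann)

sf <- size_factors(counts)
disp <- estimate_dispersion(counts, design, sf = sf)
write_tsv(disp, "results/dispersions.tsv")

contrasts <- list(c("M4B", "euploid"), c("Tri4B", "euploid"),
                  c("SegT2A", "euploid"), c("N7B+SegT2A", "SegT2A"))
de_list <- list()
for (ct in contrasts) {
  lab <- paste0(ct[1], "_vs_", ct[2])
  genes <- filter_expressed(fpkm, design, 1, ct)
  de <- nb_wald_test(counts, design, group1 = ct[2], group2 = ct[1],
                     genes = genes, sf = sf, dispersions = disp)
  de_list[[lab]] <- de
  write_tsv(de, paste0("results/de_", gsub("[^A-Za-z0-9_]", "", lab), ".tsv"))
  chr <- ann$chromosome[match(de$gene_id, ann$gene_id)]
  on <- if (ct[1] %in% c("M4B", "Tri4B")) chr == "4B" else
    if (ct[1] == "SegT2A") chr == "2A" else chr == "7B"
  message(sprintf("%s: %d expressed genes, %d DTGs (%d on the varied chromosome; %d down / %d up)",
                  lab, sum(!is.na(de$padj)), sum(de$dtg), sum(de$dtg & on),
                  sum(de$dtg & de$log2_fold_change < 0),
                  sum(de$dtg & de$log2_fold_change > 0)))
}
write_tsv(dtg_table(de_list, ann), "results/dtg_by_chromosome.tsv")
message("DTG tables written under results/")
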