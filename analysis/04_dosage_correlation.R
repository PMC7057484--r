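#!/usr/bin/env Rscript

# Dosage-correlation screen: per-gene Pearson test of per-replicate FPKM
# against chromosome copy number across M4B (1), euploid (2) and Tri4B (3),
# with BH-FDR control, then the fraction of positively dosage-correlated
# genes on the varied chromosome and inside the 2AS segment (using the
# SegT2A / N7B+SegT2A series for the segment dosage levels 2 and 4).

library(triadbuffer)
library(readr)

counts <- read_counts("results/data/counts.tsv")
ann <- read_annotation("results/data/annotation.tsv", "tsv")
design <- read_design("results/data/design.tsv")
kts <- read_karyotypes("results/data/karyotypes.tsv")
fpkm <- compute_fpkm(counts, ann)

rec_4B <- dosage_correlation_test(fpkm, design, ann, kts,
                                  genotypes = c("M4B", "euploid", "Tri4B"))
write_tsv(rec_4B, "results/dosage_test_4B_series.tsv")
fr_4B <- dosage_correlated_fraction(rec_4B, chromosome = "4B")
message(sprintf("4B series: %d of %d tested 4B genes (%.1f%%) positively dosage-correlated at FDR 0.05",
                fr_4B$n_correlated, fr_4B$n_tested, 100 * fr_4B$fraction))

rec_seg <- dosage_correlation_test(fpkm, design, ann, kts,
                                   genotypes = c("euploid", "SegT2A"))
write_tsv(rec_seg, "results/dosage_test_2AS_series.tsv")
fr_seg <- dosage_correlated_fraction(rec_seg, ann, chromosome = "2A",
                                     start = 0, end = 180e6)
message(sprintf("2AS segment: %d of %d tested segment genes (%.1f%%) dosage-correlated",
                fr_seg$n_correlated, fr_seg$n_tested, 100 * fr_seg$fraction))

write_tsv(dplyr::bind_rows(
  dplyr::mutate(fr_4B, series = "M4B/euploid/Tri4B", .before = 1),
  dplyr::mutate(fr_seg, series = "euploid/SegT2A", .before = 1)),
  "results/dosage_correlated_fractions.tsv")
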