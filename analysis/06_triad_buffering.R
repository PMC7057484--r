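#!/usr/bin/env Rscript

# Homoeolog buffering: summed triad expression, the seven-category ternary
# bias classification of euploid contributions, the one-way ANOVA for
# differentially transcribed triads (DTTs), and the buffering summaries
# contrasting gene-level DTG fractions with triad-level DTT fractions on
# the varied chromosomes. Passive buffering predicts many DTGs but few
# DTTs for whole-chromosome monosomy/trisomy.

library(triadbuffer)
library(readr)

counts <- read_counts("results/data/counts.tsv")
ann <- read_annotation("results/data/annotation.tsv", "tsv")
design <- read_design("results/data/design.tsv")
triads <- read_triads("results/data/triads.tsv")
fpkm <- compute_fpkm(counts, ann)
sf <- size_factors(counts)
disp <- estimate_dispersion(counts, design, sf = sf)

texpr <- triad_expression(fpkm, triads, design, euploid = "euploid")
write_tsv(texpr$contributions, "results/triad_contributions.tsv")
message(sprintf("%d of %d triads expressed (euploid summed FPKM > 1)",
                sum(texpr$expressed), nrow(triads)))

eu <- texpr$contributions[texpr$contributions$genotype == "euploid", ]
keep <- texpr$expressed[eu$triad_id] & complete.cases(eu[c("a", "b", "d")])
cls <- classify_bias(eu$a[keep], eu$b[keep], eu$d[keep])
cls_tab <- table(cls$category)
write_tsv(dplyr::bind_cols(tibble::tibble(triad_id = eu$triad_id[keep]),
                           cls, eu[keep, c("a", "b", "d")]),
          "results/triad_class.tsv")
message(sprintf("ternary categories: balanced %.1f%%, suppressed %.1f%%, dominant %.1f%%",
                100 * cls_tab["balanced"] / sum(cls_tab),
                100 * sum(cls_tab[grep("suppressed", names(cls_tab))]) / sum(cls_tab),
                100 * sum(cls_tab[grep("dominant", names(cls_tab))]) / sum(cls_tab)))

contrasts <- list(c("M4B", "euploid"), c("Tri4B", "euploid"),
                  c("SegT2A", "euploid"), c("N7B+SegT2A", "SegT2A"))
varied <- list(M4B = list(chr = "4B"), Tri4B = list(chr = "4B"),
               SegT2A = list(chr = "2A", start = 0, end = 180e6),
               `N7B+SegT2A` = list(chr = "7B"))
rows <- list()
for (ct in contrasts) {
  lab <- paste0(ct[1], "_vs_", ct[2])
  genes <- filter_expressed(fpkm, design, 1, ct)
  de <- nb_wald_test(counts, design, group1 = ct[2], group2 = ct[1],
                     genes = genes, sf = sf, dispersions = disp)
  dtt <- dtt_test(texpr, genotypes = ct)
  write_tsv(dtt, paste0("results/dtt_", gsub("[^A-Za-z0-9_]", "", lab), ".tsv"))
  v <- varied[[ct[1]]]
  rep_ <- buffering_report(texpr, de, dtt, ann, chromosome = v$chr,
                           start = v$start, end = v$end)
  rows[[lab]] <- dplyr::mutate(rep_$summary, contrast = lab, .before = 1)
  message(sprintf("%s: %d expressed triads on %s; DTG members %d (%.1f%%); DTTs %d (%.1f%%)",
                  lab, rep_$summary$n_expressed_triads, v$chr,
                  rep_$summary$n_dtg_members, 100 * rep_$summary$dtg_fraction,
                  rep_$summary$n_dtt, 100 * rep_$summary$dtt_fraction))
}
write_tsv(dplyr::bind_rows(rows), "results/buffering_summary.tsv")
message("triad tables written under results/")
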