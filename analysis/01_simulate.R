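#!/usr/bin/env Rscript

# Build the synthetic aneuploid series that the rest of the analysis
# consumes: a 21-chromosome allohexaploid genome at reduced scale (300 genes
# per chromosome, so every step runs in seconds), five karyotypes (euploid,
# M4B, Tri4B, SegT2A, N7B+SegT2A), three biological replicates each, and
# study-condition defaults for triad structure, dosage response and noise.

library(triadbuffer)

out <- "results/data"
cfg <- simulation_config(
  genes_per_chromosome = 300,
  replicates_per_genotype = 3,
  seed = 2020)

ds <- simulate_dataset(cfg, wheat_karyotypes())
write_dataset(ds, out)

n_resp <- sum(ds$truth$responding)
message(sprintf("simulated %d genes x %d samples (%d triads, %d dosage-responding genes)",
                nrow(ds$counts), ncol(ds$counts), nrow(ds$triads), n_resp))
message(sprintf("karyotypes: %s", paste(names(ds$karyotypes), collapse = ", ")))
message("wrote counts, annotation (TSV + GFF3), triads, design, karyotypes, truth and config under ", out)
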