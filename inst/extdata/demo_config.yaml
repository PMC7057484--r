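# Demo pipeline configuration: a small simulated aneuploid series
# (~200 genes per chromosome over homoeologous groups 1, 2, 4 and 7,
# 3 replicates) analysed with the study thresholds.
simulate:
  chromosomes: ["1A", "1B", "1D", "2A", "2B", "2D", "4A", "4B", "4D",
                "7A", "7B", "7D"]
  genes_per_chromosome: 200
  replicates_per_genotype: 3
  seed: 20
fpkm_filter: 1
fdr: 0.05
loess_span: 0.1
triad_threshold: 1
euploid: euploid
out_dir: demo_out
plots: false
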