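# Shared fixtures: small simulated datasets and hand-built matrices.

# Compact hexaploid simulation: homoeologous groups 1, 2, 4 and 7 only by
# default, enough to cover the varied chromosomes of every karyotype.
small_config <- function(genes = 80, reps = 3, seed = 42, ...) {
  simulation_config(
    chromosomes = paste0(rep(c(1, 2, 4, 7), each = 3), c("A", "B", "D")),
    genes_per_chromosome = genes,
    replicates_per_genotype = reps,
    seed = seed, ...)
}

# A deterministic annotation of a few genes at known coordinates.
toy_annotation <- function() {
  gene_annotation(
    gene_id = c("g4B_1", "g4B_2", "g2A_seg", "g2A_out", "g7B_1", "gUn_1"),
    chromosome = c("4B", "4B", "2A", "2A", "7B", "Un"),
    start = c(1e6, 2e6, 10e6, 400e6, 5e6, 0),
    end = c(1.01e6, 2.02e6, 10.02e6, 400.01e6, 5.03e6, 1e4))
}

# Design with two genotypes x n replicates and a matching count matrix
# drawn NB around given per-group means (one gene per row of `mu`).
two_group_counts <- function(mu1, mu2, n = 3, alpha = 0.05, seed = 1,
                             gene_ids = NULL) {
  set.seed(seed)
  n_genes <- length(mu1)
  draw <- function(mu) {
    if (alpha <= 0) stats::rpois(n_genes * n, rep(mu, n)) else
      stats::rnbinom(n_genes * n, mu = rep(mu, n), size = 1 / alpha)
  }
  counts <- cbind(matrix(draw(mu1), n_genes, n),
                  matrix(draw(mu2), n_genes, n))
  rownames(counts) <- gene_ids %||% paste0("g", seq_len(n_genes))
  colnames(counts) <- c(paste0("A_r", 1:n), paste0("B_r", 1:n))
  list(counts = counts,
       design = sample_design(colnames(counts),
                              rep(c("A", "B"), each = n), rep(1:n, 2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
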