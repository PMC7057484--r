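#' FPKM from raw counts
#'
#' Fragments per kilobase of gene per million mapped fragments:
#' \deqn{FPKM_{gj} = 10^9 \, K_{gj} / (N_j \, L_g)}
#' with `K` the count, `N_j` the per-sample grand total of counted fragments
#' and `L_g` the gene length in nt. No effective-length correction is
#' applied. Doubling every count of a sample leaves its FPKM column
#' unchanged (the total doubles too).
#'
#' @param counts genes x samples count matrix (rownames = gene ids).
#' @param lengths named numeric vector of gene lengths (nt), or a
#'   [gene_annotation()] tibble.
#' @return Matrix of FPKM values, genes x samples.
#' @export
compute_fpkm <- function(counts, lengths) {
  if (inherits(lengths, "tb_annotation") || is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$length, lengths$gene_id)
  }
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths)) {
    stop("missing gene length for ",
         rownames(counts)[which(is.na(lengths))[1]])
  }
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("sample ", colnames(counts)[which(totals <= 0)[1]],
         " has zero total counts")
  }
  1e9 * sweep(counts / unname(lengths), 2, totals, "/")
}

#' Replicate-averaged FPKM per genotype
#'
#' Arithmetic mean of each genotype's replicate columns, the quantity on
#' which the expression filter and the aneuploid/euploid ratios operate.
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param design a [sample_design()] tibble covering the columns of `fpkm`.
#' @return Matrix genes x genotypes.
#' @export
genotype_mean_fpkm <- function(fpkm, design) {
  design <- design[match(colnames(fpkm), design$sample), ]
  if (anyNA(design$sample)) stop("design does not cover all fpkm columns")
  genos <- unique(design$genotype)
  out <- matrix(NA_real_, nrow(fpkm), length(genos),
                dimnames = list(rownames(fpkm), genos))
  for (g in genos) {
    out[, g] <- rowMeans(fpkm[, design$sample[design$genotype == g],
                              drop = FALSE])
  }
  out
}

#' Expression filter: FPKM above unity in at least one genotype
#'
#' Keeps genes whose genotype-averaged FPKM is strictly greater than
#' `threshold` in at least one genotype. The inequality is strict ("greater
#' than unity"); raising the threshold always keeps a subset.
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param design a [sample_design()] tibble.
#' @param threshold FPKM threshold (default 1).
#' @param genotypes optional subset of genotypes over which the rule is
#'   evaluated (default all in `design`).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(fpkm, design, threshold = 1, genotypes = NULL) {
  means <- genotype_mean_fpkm(fpkm, design)
  if (!is.null(genotypes)) {
    missing <- setdiff(genotypes, colnames(means))
    if (length(missing)) stop("unknown genotype(s): ",
                              paste(missing, collapse = ", "))
    means <- means[, genotypes, drop = FALSE]
  }
  rownames(means)[apply(means > threshold, 1, any)]
}

#' Within-genotype replicate correlation
#'
#' Pearson correlation between every pair of replicates of a genotype,
#' computed on `log2(FPKM + 1)`-transformed columns; a replicate quality
#' metric. Both `r` and `R^2 = r^2` are reported. Pairs in which one sample
#' has zero variance get `NA` with a warning.
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param design a [sample_design()] tibble (>= 2 replicates per genotype).
#' @return Tibble with columns `genotype`, `sample_1`, `sample_2`, `r`,
#'   `r_squared`.
#' @export
replicate_correlation <- function(fpkm, design) {
  design <- design[design$sample %in% colnames(fpkm), ]
  lg <- log2(fpkm + 1)
  rows <- list()
  for (g in unique(design$genotype)) {
    samp <- design$sample[design$genotype == g]
    if (length(samp) < 2) {
      stop("genotype ", g, " has fewer than 2 replicates")
    }
    pairs <- utils::combn(samp, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- lg[, pairs[1, k]]; b <- lg[, pairs[2, k]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("zero-variance sample in pair ", pairs[1, k], " / ",
                pairs[2, k], "; correlation undefined", call. = FALSE)
        r <- NA_real_
      } else {
        r <- stats::cor(a, b)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        genotype = g, sample_1 = pairs[1, k], sample_2 = pairs[2, k],
        r = r, r_squared = r^2)
    }
  }
  dplyr::bind_rows(rows)
}
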