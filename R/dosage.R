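#' Per-gene Pearson test of transcript abundance against chromosome dosage
#'
#' For each gene passing the expression filter, the Pearson correlation
#' between its per-replicate FPKM and the copy number its chromosome (or
#' segment) carries in that replicate's genotype. Every replicate of a
#' genotype is an independent experimental unit, so a design with three
#' genotypes at four replicates contributes `n_units = 12` points per gene.
#' Two-sided p-values come from the t distribution with `n_units - 2`
#' degrees of freedom; Benjamini-Hochberg adjustment is applied across all
#' testable genes. Genes with zero variance in FPKM or in dosage (e.g. genes
#' on chromosomes untouched by every included karyotype) are flagged
#' untestable and excluded from the adjustment.
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param design a [sample_design()] tibble.
#' @param annotation a [gene_annotation()] tibble.
#' @param karyotypes named list of [karyotype()] objects covering the
#'   genotypes used.
#' @param genotypes genotypes to include (default: all in `design` that have
#'   a karyotype).
#' @param threshold FPKM filter threshold (default 1), evaluated over the
#'   included genotypes.
#' @param genes optional explicit gene subset replacing the filter.
#' @return Tibble with columns `gene_id`, `chromosome`, `r`, `p`, `padj`,
#'   `n_units`, `testable`.
#' @export
dosage_correlation_test <- function(fpkm, design, annotation, karyotypes,
                                    genotypes = NULL, threshold = 1,
                                    genes = NULL) {
  if (is.null(genotypes)) {
    genotypes <- intersect(unique(design$genotype), names(karyotypes))
  }
  missing <- setdiff(genotypes, names(karyotypes))
  if (length(missing)) stop("no karyotype for genotype(s): ",
                            paste(missing, collapse = ", "))
  design <- design[design$genotype %in% genotypes, ]
  fpkm <- fpkm[, design$sample, drop = FALSE]
  if (is.null(genes)) {
    genes <- filter_expressed(fpkm, design, threshold, genotypes)
  }
  genes <- intersect(genes, annotation$gene_id)
  ann <- annotation[match(genes, annotation$gene_id), ]
  Y <- fpkm[genes, , drop = FALSE]
  n <- ncol(Y)

  # per-gene dosage of each sample: dosage_of() per genotype, expanded over
  # that genotype's replicates
  D <- matrix(NA_real_, length(genes), n, dimnames = list(genes, design$sample))
  for (g in genotypes) {
    D[, design$genotype == g] <- dosage_of(karyotypes[[g]], ann)
  }

  yc <- Y - rowMeans(Y)
  dc <- D - rowMeans(D)
  sy <- rowSums(yc^2)
  sd_ <- rowSums(dc^2)
  testable <- sy > 0 & sd_ > 0 & n >= 3
  r <- rep(NA_real_, length(genes))
  r[testable] <- rowSums(yc * dc)[testable] /
    sqrt(sy[testable] * sd_[testable])
  r <- pmin(1, pmax(-1, r))
  p <- rep(NA_real_, length(genes))
  tstat <- r[testable] * sqrt((n - 2) / pmax(1 - r[testable]^2, .Machine$double.eps))
  p[testable] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  padj <- rep(NA_real_, length(genes))
  padj[testable] <- stats::p.adjust(p[testable], method = "BH")

  tibble::tibble(gene_id = genes, chromosome = ann$chromosome,
                 r = unname(r), p = unname(p), padj = unname(pmin(1, padj)),
                 n_units = n, testable = unname(testable))
}

#' Fraction of a region's genes positively correlated with dosage
#'
#' Counts genes with `r > 0` and `padj < alpha` among the testable genes of
#' a chromosome or interval, the quantity the dosage-correlation analysis
#' reports per varied chromosome or segment.
#'
#' @param records a [dosage_correlation_test()] tibble.
#' @param annotation a [gene_annotation()] tibble (needed when an interval
#'   is given).
#' @param chromosome chromosome label.
#' @param start,end optional 0-based half-open interval (gene midpoints).
#' @param alpha FDR level (default 0.05).
#' @return One-row tibble with `n_tested`, `n_correlated`, `fraction`.
#' @export
dosage_correlated_fraction <- function(records, annotation = NULL,
                                       chromosome, start = NULL, end = NULL,
                                       alpha = 0.05) {
  sel <- records$chromosome == chromosome
  if (!is.null(start) && !is.null(end)) {
    if (is.null(annotation)) stop("annotation needed for an interval region")
    ann <- annotation[match(records$gene_id, annotation$gene_id), ]
    mid <- gene_midpoint(ann)
    sel <- sel & mid >= start & mid < end
  }
  sel <- sel & records$testable
  if (!any(sel)) stop("no testable genes in the requested region on ",
                      chromosome)
  hits <- sum(records$r[sel] > 0 & records$padj[sel] < alpha, na.rm = TRUE)
  tibble::tibble(chromosome = chromosome, n_tested = sum(sel),
                 n_correlated = hits, fraction = hits / sum(sel))
}
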