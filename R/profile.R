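#' Per-gene log2(aneuploid/euploid) ratio profile
#'
#' For every gene passing the expression filter, the log2 ratio of the
#' genotype-averaged FPKM of the aneuploid over the euploid genotype,
#' positioned at the gene midpoint. Genes whose euploid (denominator) or
#' aneuploid (numerator) average is zero after filtering are excluded and
#' counted in the `dropped` attribute. Swapping the two genotypes negates
#' every ratio.
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param design a [sample_design()] tibble.
#' @param annotation a [gene_annotation()] tibble.
#' @param aneuploid,euploid genotype names present in `design`.
#' @param threshold FPKM filter threshold handed to [filter_expressed()]
#'   (applied over all genotypes in the design); default 1.
#' @param genes optional pre-computed character vector of genes to use
#'   instead of re-running the filter.
#' @return Tibble with columns `gene_id`, `chromosome`, `position`,
#'   `log2_ratio`, `contrast`; attribute `dropped` holds the number of
#'   filtered-in genes excluded for a zero mean.
#' @export
log2_ratio_profile <- function(fpkm, design, annotation, aneuploid, euploid,
                               threshold = 1, genes = NULL) {
  means <- genotype_mean_fpkm(fpkm, design)
  for (g in c(aneuploid, euploid)) {
    if (!g %in% colnames(means)) stop("unknown genotype: ", g)
  }
  if (is.null(genes)) genes <- filter_expressed(fpkm, design, threshold)
  genes <- intersect(genes, annotation$gene_id)
  num <- means[genes, aneuploid]
  den <- means[genes, euploid]
  ok <- num > 0 & den > 0
  ann <- annotation[match(genes[ok], annotation$gene_id), ]
  out <- tibble::tibble(
    gene_id = ann$gene_id,
    chromosome = ann$chromosome,
    position = gene_midpoint(ann),
    log2_ratio = unname(log2(num[ok] / den[ok])),
    contrast = paste0(aneuploid, "_vs_", euploid))
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Tri-cube local polynomial (loess) smoothing of a ratio profile
#'
#' Locally weighted polynomial regression of `log2_ratio` on `position`,
#' fitted independently per chromosome and evaluated at each gene position.
#' At each target point the `floor(span * n)` nearest genes (at least
#' `degree + 1`) receive tri-cube weights `(1 - (d/h)^3)^3` scaled by the
#' neighbourhood radius `h`, and a weighted least-squares polynomial of the
#' given degree is solved exactly; no robustness iterations are applied.
#' Chromosomes with fewer than 10 genes fall back to a single global
#' polynomial fit, with a warning.
#'
#' @param profile a [log2_ratio_profile()] tibble (or any tibble with
#'   `chromosome`, `position`, `log2_ratio`).
#' @param span fraction of points in each local neighbourhood, in (0, 1];
#'   default 0.1, the bin width used for chromosome profiles.
#' @param degree local polynomial degree (default 2).
#' @return The input tibble with a `smoothed` column appended.
#' @export
loess_smooth <- function(profile, span = 0.1, degree = 2) {
  stopifnot(span > 0, span <= 1, degree >= 0)
  out <- profile
  out$smoothed <- NA_real_
  for (chr in unique(profile$chromosome)) {
    idx <- which(profile$chromosome == chr)
    x <- profile$position[idx]
    y <- profile$log2_ratio[idx]
    n <- length(idx)
    if (n < max(10, degree + 1)) {
      warning("chromosome ", chr, ": only ", n,
              " genes; falling back to a global polynomial fit",
              call. = FALSE)
      deg <- min(degree, length(unique(x)) - 1)
      out$smoothed[idx] <- stats::lm.fit(poly_basis(x, deg), y)$fitted.values
      next
    }
    out$smoothed[idx] <- tricube_local_fit(x, y, x, span = span,
                                           degree = degree)
  }
  out
}

# Exact tri-cube weighted local polynomial regression: one WLS solve per
# evaluation point. x need not be sorted; ties in position are handled by
# widening the bandwidth to the first strictly larger distance.
tricube_local_fit <- function(x, y, x_eval, span, degree) {
  n <- length(x)
  q <- max(degree + 1, min(n, floor(span * n)))
  fitted <- numeric(length(x_eval))
  for (k in seq_along(x_eval)) {
    x0 <- x_eval[k]
    d <- abs(x - x0)
    h <- sort(d, partial = q)[q]
    if (h == 0) {
      # q-th neighbour coincides with the target: average the coincident points
      fitted[k] <- mean(y[d == 0])
      next
    }
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    deg <- min(degree, length(unique(x[use])) - 1)
    fit <- stats::lm.wfit(poly_basis((x - x0)[use], deg), y[use], w[use])
    fitted[k] <- fit$coefficients[1]
  }
  fitted
}

# 1, t, t^2, ... design matrix; degree 0 gives the intercept column alone.
poly_basis <- function(t, degree) {
  X <- matrix(1, length(t), degree + 1)
  if (degree >= 1) for (p in seq_len(degree)) X[, p + 1] <- t^p
  X
}

#' Median and mean log2 ratio over a chromosome or interval
#'
#' @param profile a [log2_ratio_profile()] tibble.
#' @param chromosome chromosome label.
#' @param start,end optional 0-based half-open interval restricting the
#'   region (gene midpoints inside the interval); `NULL` = whole chromosome.
#' @param invert if `TRUE`, summarize the genes of `chromosome` *outside*
#'   the interval instead.
#' @return One-row tibble with `n_genes`, `median_log2_ratio`,
#'   `mean_log2_ratio`.
#' @export
region_summary <- function(profile, chromosome, start = NULL, end = NULL,
                           invert = FALSE) {
  sel <- profile$chromosome == chromosome
  if (!is.null(start) && !is.null(end)) {
    inside <- profile$position >= start & profile$position < end
    sel <- sel & (if (invert) !inside else inside)
  }
  if (!any(sel)) stop("no genes in the requested region on ", chromosome)
  r <- profile$log2_ratio[sel]
  tibble::tibble(chromosome = chromosome,
                 n_genes = sum(sel),
                 median_log2_ratio = stats::median(r),
                 mean_log2_ratio = mean(r))
}

#' Plot a chromosome ratio profile with its smoothed curve
#'
#' One panel per chromosome: per-gene log2(aneuploid/euploid) ratios against
#' physical position, with the tri-cube smoothed curve overlaid and the
#' dosage guide lines 0, 0.585 (log2 1.5), -1 (log2 0.5) and 1 (log2 2).
#'
#' @param profile a [loess_smooth()] (or [log2_ratio_profile()]) tibble.
#' @param chromosomes optional subset of chromosomes to draw.
#' @return A ggplot object.
#' @export
plot_ratio_profile <- function(profile, chromosomes = NULL) {
  if (!is.null(chromosomes)) {
    profile <- profile[profile$chromosome %in% chromosomes, ]
  }
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$position / 1e6,
                                    y = .data$log2_ratio)) +
    ggplot2::geom_hline(yintercept = c(-1, 0, log2(1.5), 1),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_point(size = 0.3, alpha = 0.3) +
    ggplot2::facet_wrap(~chromosome, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = expression(log[2]("aneuploid/euploid"))) +
    ggplot2::theme_minimal()
  if ("smoothed" %in% names(profile)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                                colour = "firebrick", linewidth = 0.6)
  }
  p
}
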