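#' Median-of-ratios size factors
#'
#' Per-sample scale factor: the median, over genes with nonzero counts in
#' every sample, of the ratio of the sample's count to the gene's geometric
#' mean across samples. The factors of a matrix whose columns are identical
#' are all 1, and the log factors are centred by construction of the
#' geometric-mean reference.
#'
#' @param counts genes x samples count matrix.
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no gene has nonzero counts in every sample; supply counts with a ",
         "common reference set (pseudo-reference fallback not implemented)")
  }
  loggeo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  sf <- apply(counts[all_pos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - loggeo))
  })
  sf
}

#' Method-of-moments dispersion estimates with trend shrinkage
#'
#' Per-gene negative-binomial dispersion from within-group means and
#' variances of size-factor-normalized counts: for each group with at least
#' two replicates, `alpha = (var - mean * z) / mean^2` with `z` the group
#' mean of `1/s_j` (the Poisson variance of a normalized count), combined
#' across groups with `n_g - 1` weights and floored at `1e-8`. The raw
#' estimates are then shrunk on the log scale toward a fitted
#' mean-dispersion trend `a0 + a1 / mean` with weight `shrink` (default
#' 0.5), stabilizing the genewise estimates at the small replicate numbers
#' the design provides.
#'
#' @param counts genes x samples count matrix.
#' @param design a [sample_design()] tibble; at least one genotype needs
#'   >= 2 replicates.
#' @param sf size factors (default [size_factors()] of `counts`).
#' @param shrink weight of the trend in the log-scale shrinkage, in [0, 1].
#' @return Tibble with `gene_id`, `base_mean`, `alpha_mom`, `alpha_trend`,
#'   `alpha` (the shrunk estimate used by [nb_wald_test()]).
#' @export
estimate_dispersion <- function(counts, design, sf = NULL, shrink = 0.5) {
  design <- design[match(colnames(counts), design$sample), ]
  reps <- table(design$genotype)
  if (!any(reps >= 2)) {
    stop("dispersion estimation needs at least one genotype with >= 2 replicates")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  num <- den <- numeric(nrow(counts))
  for (g in names(reps)[reps >= 2]) {
    cols <- design$sample[design$genotype == g]
    sub <- norm[, cols, drop = FALSE]
    m <- rowMeans(sub)
    v <- rowSums((sub - m)^2) / (length(cols) - 1)
    z <- mean(1 / sf[cols])
    w <- length(cols) - 1
    ok <- m > 0
    num[ok] <- num[ok] + w * (v[ok] - m[ok] * z) / m[ok]^2
    den[ok] <- den[ok] + w
  }
  alpha_mom <- ifelse(den > 0, pmax(num / pmax(den, 1), 1e-8), NA_real_)
  base_mean <- rowMeans(norm)

  # mean-dispersion trend alpha(mu) = a0 + a1/mu, fitted on informative genes
  fit_ok <- !is.na(alpha_mom) & alpha_mom > 1e-8 & base_mean > 0
  if (sum(fit_ok) >= 10) {
    co <- stats::coef(stats::lm(alpha_mom[fit_ok] ~ I(1 / base_mean[fit_ok])))
    a0 <- max(co[1], 1e-8); a1 <- max(co[2], 0)
  } else {
    a0 <- stats::median(alpha_mom, na.rm = TRUE); a1 <- 0
  }
  alpha_trend <- a0 + a1 / pmax(base_mean, 1e-8)
  alpha <- exp((1 - shrink) * log(pmax(alpha_mom, 1e-8)) +
                 shrink * log(alpha_trend))
  tibble::tibble(gene_id = rownames(counts), base_mean = base_mean,
                 alpha_mom = alpha_mom, alpha_trend = alpha_trend,
                 alpha = ifelse(is.na(alpha_mom), alpha_trend, alpha))
}

#' Negative-binomial Wald test for differential transcription
#'
#' A transparent two-group NB test on raw counts: median-of-ratios
#' normalization, genewise dispersions from [estimate_dispersion()], log2
#' fold change of normalized group means (pseudocount 1/2 on both means, for
#' the reported LFC only), and a Wald statistic
#' `log2(m2/m1) / SE` with the delta-method standard error
#' \deqn{SE^2 = \frac{1}{\ln^2 2}\left(\frac{\widehat{Var}(\bar m_1)}{m_1^2}
#'   + \frac{\widehat{Var}(\bar m_2)}{m_2^2}\right),\qquad
#'   \widehat{Var}(\bar m_g) = \frac{1}{n_g^2}\sum_j
#'   \left(\frac{m_g}{s_j} + \frac{\alpha_g m_g^2}{s_j^2}\right)}
#' i.e. the NB variance of each normalized replicate evaluated at the group
#' mean. Two-sided p-values are normal; Benjamini-Hochberg adjustment runs
#' over the tested genes (those in `genes`, default: nonzero in at least one
#' of the two groups). Genes zero in both groups are untested. Swapping the
#' group labels negates every LFC and leaves the p-values unchanged. A gene
#' is a differentially transcribed gene (DTG) when `padj < alpha_fdr`.
#'
#' @param counts genes x samples count matrix.
#' @param design a [sample_design()] tibble.
#' @param group1,group2 genotype names: the contrast is `group2` vs
#'   `group1` (LFC > 0 means higher in `group2`).
#' @param genes optional gene subset over which to test and adjust
#'   (typically the expression-filtered set of the contrast).
#' @param sf size factors for the full matrix (default computed).
#' @param dispersions optional [estimate_dispersion()] result.
#' @param alpha_fdr FDR threshold for the `dtg` flag (default 0.05).
#' @return Tibble with `gene_id`, `base_mean`, `log2_fold_change`, `se`,
#'   `stat`, `p`, `padj`, `dtg`.
#' @export
nb_wald_test <- function(counts, design, group1, group2, genes = NULL,
                         sf = NULL, dispersions = NULL, alpha_fdr = 0.05) {
  design <- design[match(colnames(counts), design$sample), ]
  for (g in c(group1, group2)) {
    if (!g %in% design$genotype) stop("unknown genotype: ", g)
  }
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(counts, design, sf = sf)
  }
  alpha <- stats::setNames(dispersions$alpha, dispersions$gene_id)[rownames(counts)]
  if (!is.null(genes)) {
    counts <- counts[intersect(genes, rownames(counts)), , drop = FALSE]
    alpha <- alpha[rownames(counts)]
  }
  cols1 <- design$sample[design$genotype == group1]
  cols2 <- design$sample[design$genotype == group2]
  norm <- sweep(counts, 2, sf[colnames(counts)], "/")
  m1 <- rowMeans(norm[, cols1, drop = FALSE])
  m2 <- rowMeans(norm[, cols2, drop = FALSE])
  tested <- m1 > 0 | m2 > 0

  lfc <- log2((m2 + 0.5) / (m1 + 0.5))

  # delta-method variance of a group mean of normalized counts, at the group
  # mean; zero-mean groups fall back to the pseudocounted mean so that
  # one-sided zeros stay testable with a finite statistic
  var_mean <- function(mu, cols) {
    a <- sum(1 / sf[cols]) / length(cols)^2
    b <- sum(1 / sf[cols]^2) / length(cols)^2
    mu * a + alpha * mu^2 * b
  }
  m1t <- ifelse(m1 > 0, m1, NA); m2t <- ifelse(m2 > 0, m2, NA)
  one_sided_zero <- tested & (m1 == 0 | m2 == 0)
  m1t[one_sided_zero] <- m1[one_sided_zero] + 0.5
  m2t[one_sided_zero] <- m2[one_sided_zero] + 0.5
  v1 <- var_mean(m1t, cols1)
  v2 <- var_mean(m2t, cols2)
  se <- sqrt((v1 / m1t^2 + v2 / m2t^2)) / log(2)
  stat <- log2(m2t / m1t) / se
  p <- 2 * stats::pnorm(-abs(stat))
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- stats::p.adjust(p[tested], method = "BH")
  tibble::tibble(gene_id = rownames(counts),
                 base_mean = unname(rowMeans(norm)),
                 log2_fold_change = unname(ifelse(tested, lfc, NA_real_)),
                 se = unname(ifelse(tested, se, NA_real_)),
                 stat = unname(ifelse(tested, stat, NA_real_)),
                 p = unname(p), padj = unname(padj),
                 dtg = unname(!is.na(padj) & padj < alpha_fdr))
}

#' Chromosomal distribution of DTGs
#'
#' Cross-tabulates the down- and upregulated DTGs of one or more contrasts
#' by chromosome, the layout in which chromosomal DTG distributions are
#' reported (chromosome columns, Down/Up rows per contrast).
#'
#' @param de_records named list of [nb_wald_test()] tibbles (names =
#'   contrast labels), or a single tibble.
#' @param annotation a [gene_annotation()] tibble.
#' @return Tibble with `contrast`, `regulation`, one column per chromosome,
#'   and `total`.
#' @export
dtg_table <- function(de_records, annotation) {
  if (is.data.frame(de_records)) de_records <- list(contrast = de_records)
  chroms <- c(wheat_chromosomes(), "Un")
  rows <- list()
  for (ctr in names(de_records)) {
    de <- de_records[[ctr]]
    chr <- annotation$chromosome[match(de$gene_id, annotation$gene_id)]
    for (dir in c("Down", "Up")) {
      hit <- de$dtg & !is.na(de$log2_fold_change) &
        (if (dir == "Down") de$log2_fold_change < 0 else de$log2_fold_change > 0)
      counts <- table(factor(chr[hit], levels = chroms))
      row <- tibble::as_tibble(as.list(as.integer(counts)), .name_repair = "minimal")
      names(row) <- chroms
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(contrast = ctr, regulation = dir), row,
        tibble::tibble(total = sum(hit)))
    }
  }
  dplyr::bind_rows(rows)
}
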