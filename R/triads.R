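#' Triad expression: summed homoeoallele FPKM and relative contributions
#'
#' For every triad, the per-sample sum of its three members' FPKM, the
#' per-genotype mean total, and the per-genotype relative contributions
#' `(a, b, d)` of the A, B and D members (each genotype's member means
#' divided by their sum, so the three contributions are nonnegative and sum
#' to 1). A triad counts as transcribed ("expressed") when its euploid
#' genotype-mean total exceeds `threshold` (default 1 FPKM); the rule keeps
#' triads in which only one member is transcribed. Members absent from the
#' matrix contribute 0 with a warning.
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param triads a [triad_catalog()] tibble.
#' @param design a [sample_design()] tibble.
#' @param euploid name of the reference genotype for the expressed rule.
#' @param threshold summed-FPKM expression threshold (default 1, strict).
#' @return A list of class `tb_triad_expression`: `totals` (triads x
#'   samples), `genotype_totals` (triads x genotypes), `contributions`
#'   (tibble: triad_id, genotype, a, b, d), `expressed` (named logical),
#'   `triads`, `design`.
#' @export
triad_expression <- function(fpkm, triads, design, euploid = "euploid",
                             threshold = 1) {
  if (!euploid %in% design$genotype) {
    stop("euploid genotype \"", euploid, "\" absent from the design")
  }
  members <- c(triads$A, triads$B, triads$D)
  absent <- setdiff(members, rownames(fpkm))
  if (length(absent)) {
    warning(length(absent), " triad member gene(s) absent from the FPKM ",
            "matrix; treated as unexpressed (0)", call. = FALSE)
  }
  get <- function(ids) {
    m <- matrix(0, length(ids), ncol(fpkm), dimnames = list(ids, colnames(fpkm)))
    hit <- ids %in% rownames(fpkm)
    m[hit, ] <- fpkm[ids[hit], , drop = FALSE]
    m
  }
  A <- get(triads$A); B <- get(triads$B); D <- get(triads$D)
  totals <- A + B + D
  rownames(totals) <- triads$triad_id
  design <- design[match(colnames(fpkm), design$sample), ]
  genos <- unique(design$genotype)
  gmean <- function(m) {
    out <- matrix(NA_real_, nrow(m), length(genos),
                  dimnames = list(triads$triad_id, genos))
    for (g in genos) {
      out[, g] <- rowMeans(m[, design$sample[design$genotype == g],
                             drop = FALSE])
    }
    out
  }
  gt <- gmean(totals); ga <- gmean(A); gb <- gmean(B); gd <- gmean(D)
  contrib <- dplyr::bind_rows(lapply(genos, function(g) {
    tot <- gt[, g]
    tibble::tibble(triad_id = triads$triad_id, genotype = g,
                   a = ifelse(tot > 0, ga[, g] / tot, NA_real_),
                   b = ifelse(tot > 0, gb[, g] / tot, NA_real_),
                   d = ifelse(tot > 0, gd[, g] / tot, NA_real_))
  }))
  expressed <- gt[, euploid] > threshold
  structure(list(totals = totals, genotype_totals = gt,
                 contributions = contrib,
                 expressed = stats::setNames(expressed, triads$triad_id),
                 triads = triads, design = design),
            class = "tb_triad_expression")
}

#' @export
print.tb_triad_expression <- function(x, ...) {
  cat("<triad expression> ", nrow(x$totals), " triads x ", ncol(x$totals),
      " samples; ", sum(x$expressed), " expressed\n", sep = "")
  invisible(x)
}

# the seven ideal expression patterns on the (a, b, d) simplex, in the fixed
# tie-break order
bias_centroids <- function() {
  rbind(balanced      = c(1, 1, 1) / 3,
        `A-dominant`  = c(1, 0, 0),
        `B-dominant`  = c(0, 1, 0),
        `D-dominant`  = c(0, 0, 1),
        `A-suppressed` = c(0, 1, 1) / 2,
        `B-suppressed` = c(1, 0, 1) / 2,
        `D-suppressed` = c(1, 1, 0) / 2)
}

#' Seven-category ternary bias classification
#'
#' Assigns relative homoeoallele contributions `(a, b, d)` to the nearest of
#' seven ideal patterns by Euclidean distance on the simplex: balanced
#' (1/3, 1/3, 1/3), one-homoeoallele-dominant ((1,0,0)-type) and
#' one-homoeoallele-suppressed ((0,1/2,1/2)-type). Exact distance ties are
#' broken by the fixed order balanced, A-dominant, B-dominant, D-dominant,
#' A-suppressed, B-suppressed, D-suppressed. Relabeling the subgenomes
#' permutes the categories correspondingly and leaves all distances
#' unchanged.
#'
#' @param a,b,d contribution vectors; each triple must be nonnegative and
#'   sum to 1 (tolerance 1e-6).
#' @return Tibble with `category` (factor over the seven labels) and one
#'   distance column per centroid (`dist_balanced`, ...).
#' @export
classify_bias <- function(a, b, d) {
  P <- cbind(a, b, d)
  if (anyNA(P) || any(P < -1e-9) || any(abs(rowSums(P) - 1) > 1e-6)) {
    stop("contributions must be nonnegative and sum to 1")
  }
  C <- bias_centroids()
  # squared distances via expansion: |p|^2 - 2 p.c + |c|^2
  D2 <- matrix(rowSums(P^2), nrow(P), nrow(C)) -
    2 * P %*% t(C) + matrix(rowSums(C^2), nrow(P), nrow(C), byrow = TRUE)
  cat_idx <- apply(D2, 1, which.min)   # which.min takes the first = tie order
  dist <- sqrt(pmax(D2, 0))
  colnames(dist) <- paste0("dist_", sub("-", "_", rownames(C)))
  dplyr::bind_cols(
    tibble::tibble(category = factor(rownames(C)[cat_idx],
                                     levels = rownames(C))),
    tibble::as_tibble(dist))
}

#' One-way ANOVA for differentially transcribed triads (DTTs)
#'
#' Per-triad one-way ANOVA of the per-replicate summed homoeoallele FPKM
#' across genotypes, computed on the expressed triads; p-values are BH
#' adjusted and a triad is a DTT when `padj < alpha_fdr`. Both the raw and
#' adjusted p-values are reported. Triads with zero variance everywhere are
#' untestable (`NA`).
#'
#' @param triad_expr a [triad_expression()] object.
#' @param genotypes genotypes to compare (default: all in the design).
#' @param alpha_fdr FDR threshold for the `dtt` flag (default 0.05).
#' @param expressed_only restrict testing and adjustment to expressed
#'   triads (default `TRUE`).
#' @return Tibble with `triad_id`, `f`, `p`, `padj`, `dtt`.
#' @export
dtt_test <- function(triad_expr, genotypes = NULL, alpha_fdr = 0.05,
                     expressed_only = TRUE) {
  design <- triad_expr$design
  if (is.null(genotypes)) genotypes <- unique(design$genotype)
  design <- design[design$genotype %in% genotypes, ]
  if (length(unique(design$genotype)) < 2) {
    stop("the triad ANOVA needs at least 2 genotypes")
  }
  if (any(table(design$genotype) < 2)) {
    stop("the triad ANOVA needs >= 2 replicates per genotype")
  }
  Y <- triad_expr$totals[, design$sample, drop = FALSE]
  if (expressed_only) Y <- Y[triad_expr$expressed, , drop = FALSE]
  grp <- factor(design$genotype)
  k <- nlevels(grp); n <- ncol(Y)
  gm <- rowMeans(Y)
  ssb <- 0
  ssw <- 0
  for (lev in levels(grp)) {
    cols <- which(grp == lev)
    m <- rowMeans(Y[, cols, drop = FALSE])
    ssb <- ssb + length(cols) * (m - gm)^2
    ssw <- ssw + rowSums((Y[, cols, drop = FALSE] - m)^2)
  }
  df1 <- k - 1; df2 <- n - k
  testable <- ssw > 0
  f <- ifelse(testable, (ssb / df1) / (ssw / df2), NA_real_)
  p <- ifelse(testable, stats::pf(f, df1, df2, lower.tail = FALSE), NA_real_)
  padj <- rep(NA_real_, length(p))
  padj[testable] <- stats::p.adjust(p[testable], method = "BH")
  tibble::tibble(triad_id = rownames(Y), f = unname(f), p = unname(p),
                 padj = unname(padj),
                 dtt = unname(!is.na(padj) & padj < alpha_fdr))
}

#' Buffering summary for one aneuploid-vs-euploid contrast
#'
#' Assembles the triad-level view of a contrast: the expressed triads whose
#' member on the varied subgenome lies in the dosage-varied region, their
#' DTG members (from the gene-level NB Wald test), the DTT calls, the
#' category-by-DTT cross-table, and the mean contribution of the varied
#' subgenome among DTTs vs non-DTTs.
#'
#' @param triad_expr a [triad_expression()] object.
#' @param de a [nb_wald_test()] tibble for the contrast.
#' @param dtt a [dtt_test()] tibble for the genotype pair.
#' @param annotation a [gene_annotation()] tibble.
#' @param classes a [classify_bias()] result aligned with the expressed
#'   triads in euploid contributions (optional; computed when `NULL`).
#' @param chromosome varied chromosome label.
#' @param start,end optional varied interval (0-based half-open midpoints).
#' @param euploid reference genotype for contributions (default
#'   `"euploid"`).
#' @return A list of class `tb_buffering_summary`: `summary` (one-row
#'   tibble: expressed triads in the region, DTG count/fraction among their
#'   varied-subgenome members, DTT count/fraction), `by_category`
#'   (category x DTT cross-table), `contrib_comparison` (mean varied-
#'   subgenome contribution among DTTs vs non-DTTs).
#' @export
buffering_report <- function(triad_expr, de, dtt, annotation, chromosome,
                             start = NULL, end = NULL, classes = NULL,
                             euploid = "euploid") {
  triads <- triad_expr$triads
  sg <- subgenome_of(chromosome)
  if (!sg %in% c("A", "B", "D")) stop("varied chromosome must be 1A..7D")
  member <- triads[[sg]]
  ann <- annotation[match(member, annotation$gene_id), ]
  in_region <- ann$chromosome == chromosome
  if (!is.null(start) && !is.null(end)) {
    mid <- gene_midpoint(ann)
    in_region <- in_region & mid >= start & mid < end
  }
  in_region[is.na(in_region)] <- FALSE
  sel <- in_region & triad_expr$expressed[triads$triad_id]
  ids <- triads$triad_id[sel]
  if (!length(ids)) stop("no expressed triads with their ", sg,
                         " member in the varied region of ", chromosome)

  de_idx <- match(member[sel], de$gene_id)
  dtg_flag <- !is.na(de_idx) & de$dtg[pmax(de_idx, 1)]
  dtt_idx <- match(ids, dtt$triad_id)
  dtt_flag <- !is.na(dtt_idx) & dtt$dtt[pmax(dtt_idx, 1)]

  contrib <- triad_expr$contributions
  eu <- contrib[contrib$genotype == euploid, ]
  eu <- eu[match(ids, eu$triad_id), ]
  if (is.null(classes)) {
    ok <- stats::complete.cases(eu[c("a", "b", "d")])
    classes <- tibble::tibble(category = factor(rep(NA_character_, nrow(eu)),
                                                levels = rownames(bias_centroids())))
    if (any(ok)) classes$category[ok] <-
        classify_bias(eu$a[ok], eu$b[ok], eu$d[ok])$category
  }
  varied_contrib <- eu[[tolower(sg)]]

  summary <- tibble::tibble(
    chromosome = chromosome, subgenome = sg,
    n_expressed_triads = length(ids),
    n_dtg_members = sum(dtg_flag),
    dtg_fraction = mean(dtg_flag),
    n_dtt = sum(dtt_flag),
    dtt_fraction = mean(dtt_flag))
  by_category <- as.data.frame(table(category = classes$category,
                                     dtt = dtt_flag))
  contrib_comparison <- tibble::tibble(
    group = c("DTT", "non-DTT"),
    n = c(sum(dtt_flag), sum(!dtt_flag)),
    mean_varied_contribution = c(mean(varied_contrib[dtt_flag], na.rm = TRUE),
                                 mean(varied_contrib[!dtt_flag], na.rm = TRUE)))
  structure(list(summary = summary, by_category = tibble::as_tibble(by_category),
                 contrib_comparison = contrib_comparison,
                 triad_ids = ids, dtg = dtg_flag, dtt = dtt_flag,
                 varied_contribution = varied_contrib,
                 category = classes$category),
            class = "tb_buffering_summary")
}

#' @export
print.tb_buffering_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Ternary plot coordinates
#'
#' Projects simplex contributions `(a, b, d)` to 2-D ternary coordinates
#' (A bottom-left, B bottom-right, D top).
#'
#' @param a,b,d contribution vectors summing to 1.
#' @return Tibble with `x`, `y`.
#' @export
ternary_coords <- function(a, b, d) {
  tibble::tibble(x = b + d / 2, y = d * sqrt(3) / 2)
}

#' Ternary plot of triad contributions
#'
#' @param contributions tibble with columns `a`, `b`, `d` and optionally
#'   `category` (used for colour).
#' @return A ggplot object.
#' @export
plot_ternary <- function(contributions) {
  cc <- contributions[stats::complete.cases(contributions[c("a", "b", "d")]), ]
  xy <- ternary_coords(cc$a, cc$b, cc$d)
  cc <- dplyr::bind_cols(cc, xy)
  frame <- tibble::tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  p <- ggplot2::ggplot(cc, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = frame, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y), colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::annotate("text", x = c(-0.03, 1.03, 0.5), y = c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
                      label = c("A", "B", "D"), fontface = "bold")
  if ("category" %in% names(cc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$category),
                            size = 0.5, alpha = 0.6)
  } else {
    p + ggplot2::geom_point(size = 0.5, alpha = 0.6)
  }
}
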