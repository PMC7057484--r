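#' Pipeline configuration
#'
#' A single configuration object driving [run_pipeline()]: either a
#' `simulate` block (a [simulation_config()]) or paths to input files, a
#' list of contrasts (aneuploid vs reference genotype pairs), the analysis
#' thresholds, and an output directory. Configurations validate before any
#' stage runs.
#'
#' @param simulate a [simulation_config()], or `NULL` when `inputs` are
#'   given.
#' @param inputs named list of file paths (`counts`, `annotation`, `triads`,
#'   `karyotypes`, `design`), used when `simulate` is `NULL`.
#' @param karyotypes named list of [karyotype()] objects (default
#'   [wheat_karyotypes()]); must include `"euploid"`.
#' @param contrasts list of length-2 character vectors
#'   `c(aneuploid, reference)`; default: every non-reference genotype
#'   against `"euploid"`, plus `N7B+SegT2A` vs `SegT2A` when both exist.
#' @param fpkm_filter FPKM expression threshold (default 1).
#' @param fdr FDR level for every adjusted test (default 0.05).
#' @param loess_span smoother span for the chromosome profiles (default
#'   0.1).
#' @param triad_threshold summed-FPKM threshold for expressed triads
#'   (default 1).
#' @param euploid name of the reference genotype (default `"euploid"`).
#' @param out_dir output directory for the emitted tables.
#' @param plots write profile and ternary plots as PDF (default `FALSE`).
#' @return A validated list of class `tb_pipeline_config`.
#' @export
pipeline_config <- function(simulate = simulation_config(),
                            inputs = NULL,
                            karyotypes = wheat_karyotypes(),
                            contrasts = NULL,
                            fpkm_filter = 1, fdr = 0.05, loess_span = 0.1,
                            triad_threshold = 1, euploid = "euploid",
                            out_dir = "pipeline_out", plots = FALSE) {
  if (is.null(simulate) && is.null(inputs)) {
    stop("pipeline config needs either a simulate block or input paths")
  }
  if (!euploid %in% names(karyotypes)) {
    stop("pipeline config invalid: no karyotype named \"", euploid, "\"")
  }
  if (is.null(contrasts)) {
    others <- setdiff(names(karyotypes), euploid)
    contrasts <- lapply(setdiff(others, "N7B+SegT2A"), function(g) c(g, euploid))
    if (all(c("N7B+SegT2A", "SegT2A") %in% names(karyotypes))) {
      contrasts <- c(contrasts, list(c("N7B+SegT2A", "SegT2A")))
    }
  }
  for (ct in contrasts) {
    if (length(ct) != 2 || !all(ct %in% names(karyotypes))) {
      stop("pipeline config invalid: contrast (",
           paste(ct, collapse = " vs "), ") references undeclared genotypes")
    }
  }
  stopifnot(fpkm_filter >= 0, fdr > 0, fdr < 1, loess_span > 0,
            loess_span <= 1)
  structure(list(simulate = simulate, inputs = inputs,
                 karyotypes = karyotypes, contrasts = contrasts,
                 fpkm_filter = fpkm_filter, fdr = fdr,
                 loess_span = loess_span, triad_threshold = triad_threshold,
                 euploid = euploid, out_dir = out_dir, plots = plots),
            class = "tb_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML mirrors the arguments of [pipeline_config()]; the `simulate`
#' block maps to [simulation_config()] fields, `karyotypes` may name the
#' bundled aneuploid series (`preset: wheat`) or spell out overrides per
#' genotype.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    sim <- do.call(simulation_config, y$simulate)
  }
  kts <- wheat_karyotypes()
  if (!is.null(y$karyotypes) && is.null(y$karyotypes$preset)) {
    kts <- lapply(names(y$karyotypes), function(nm) {
      spec <- y$karyotypes[[nm]]
      ov <- if (!is.null(spec$overrides)) {
        dplyr::bind_rows(lapply(spec$overrides, tibble::as_tibble))
      } else NULL
      karyotype(nm, baseline_copy = spec$baseline_copy %||% 2, overrides = ov)
    })
    names(kts) <- names(y$karyotypes)
  }
  args <- y[intersect(names(y), c("fpkm_filter", "fdr", "loess_span",
                                  "triad_threshold", "euploid", "out_dir",
                                  "plots"))]
  args$simulate <- sim
  args$inputs <- y$inputs
  args$karyotypes <- kts
  if (!is.null(y$contrasts)) args$contrasts <- y$contrasts
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The chromosome/segment whose copy number differs between two karyotypes:
# the first override of either side whose copy number is not matched by the
# other karyotype over the same region. NULL when the karyotypes agree.
varied_region <- function(kt, ref) {
  cand <- dplyr::bind_rows(kt$overrides, ref$overrides)
  if (!nrow(cand)) return(NULL)
  for (i in seq_len(nrow(cand))) {
    probe_pos <- if (is.na(cand$start[i])) 1 else (cand$start[i] + cand$end[i]) / 2
    probe <- gene_annotation("probe", cand$chromosome[i], probe_pos,
                             probe_pos + 1)
    if (dosage_of(kt, probe) != dosage_of(ref, probe)) {
      return(list(chromosome = cand$chromosome[i],
                  start = if (is.na(cand$start[i])) NULL else cand$start[i],
                  end = if (is.na(cand$end[i])) NULL else cand$end[i]))
    }
  }
  NULL
}

#' Run the full dosage/buffering pipeline
#'
#' Executes every stage in dependency order — simulate (or load), FPKM
#' quantification and replicate QC, expression filtering, per-contrast
#' chromosome ratio profiles with tri-cube smoothing, the dosage Pearson
#' test, the NB Wald differential-transcription test, triad expression,
#' ternary classification, the triad ANOVA and the buffering summaries —
#' and writes each result as a TSV under `config$out_dir`. Each table
#' carries `#`-prefixed header lines naming the producing stage and its
#' parameters; a `run_log.txt` records gene counts at every filter so that
#' filtered-out plus retained always equals the stage input. Runs are
#' deterministic given the simulation seed.
#'
#' @param config a [pipeline_config()] object.
#' @return Invisibly, a list with every in-memory stage result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tb_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  cat("", file = log_path)
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  emit <- function(tab, name, stage, ...) {
    path <- file.path(config$out_dir, name)
    hdr <- c(paste0("# stage: ", stage),
             paste0("# params: ", paste(..., sep = "; ")))
    writeLines(hdr, path)
    suppressWarnings(readr::write_tsv(tab, path, append = TRUE,
                                      col_names = TRUE))
    path
  }

  ## stage: data
  if (!is.null(config$simulate)) {
    logf("simulate: seed %d", config$simulate$seed)
    ds <- simulate_dataset(config$simulate, config$karyotypes)
    readr::write_tsv(ds$truth, file.path(config$out_dir, "truth.tsv"))
  } else {
    logf("load: %s", config$inputs$counts)
    ds <- list(counts = read_counts(config$inputs$counts),
               annotation = read_annotation(config$inputs$annotation),
               triads = read_triads(config$inputs$triads),
               design = read_design(config$inputs$design),
               karyotypes = read_karyotypes(config$inputs$karyotypes))
  }
  counts <- ds$counts; ann <- ds$annotation; design <- ds$design
  logf("data: %d genes x %d samples, %d triads", nrow(counts), ncol(counts),
       nrow(ds$triads))

  ## stage: quantification
  fpkm <- compute_fpkm(counts, ann)
  gmeans <- genotype_mean_fpkm(fpkm, design)
  emit(dplyr::bind_cols(tibble::tibble(gene_id = rownames(fpkm)),
                        tibble::as_tibble(fpkm)),
       "fpkm.tsv", "quantification", "fpkm = 1e9*count/(total*length)")
  emit(dplyr::bind_cols(tibble::tibble(gene_id = rownames(gmeans)),
                        tibble::as_tibble(gmeans)),
       "fpkm_by_genotype.tsv", "quantification", "replicate-averaged")
  qc <- replicate_correlation(fpkm, design)
  emit(qc, "replicate_qc.tsv", "quantification", "pearson on log2(FPKM+1)")
  logf("replicate QC: mean R^2 = %.3f", mean(qc$r_squared, na.rm = TRUE))

  expressed <- filter_expressed(fpkm, design, config$fpkm_filter)
  logf("expression filter (FPKM > %g): %d kept + %d dropped = %d",
       config$fpkm_filter, length(expressed),
       nrow(fpkm) - length(expressed), nrow(fpkm))

  ## stage: profiles per contrast
  profiles <- list()
  for (ct in config$contrasts) {
    lab <- paste0(ct[1], "_vs_", ct[2])
    genes_ct <- filter_expressed(fpkm, design, config$fpkm_filter, ct)
    prof <- log2_ratio_profile(fpkm, design, ann, ct[1], ct[2],
                               genes = genes_ct)
    smoothed <- loess_smooth(prof, span = config$loess_span)
    profiles[[lab]] <- smoothed
    emit(prof, paste0("ratios_", gsub("[^A-Za-z0-9_]", "", lab), ".tsv"),
         "dosage_profiling", paste0("contrast = ", lab),
         paste0("filter FPKM > ", config$fpkm_filter))
    emit(smoothed[c("gene_id", "chromosome", "position", "smoothed")],
         paste0("smoothed_", gsub("[^A-Za-z0-9_]", "", lab), ".tsv"),
         "dosage_profiling", paste0("span = ", config$loess_span, ", degree 2"))
    logf("profile %s: %d genes (%d zero-mean excluded)", lab, nrow(prof),
         attr(prof, "dropped"))
    if (config$plots) {
      ggplot2::ggsave(file.path(config$out_dir, paste0("profile_", gsub(
        "[^A-Za-z0-9_]", "", lab), ".pdf")),
        plot_ratio_profile(smoothed), width = 11, height = 8)
    }
  }

  ## stage: dosage correlation across all genotypes
  dosage <- dosage_correlation_test(fpkm, design, ann, config$karyotypes,
                                    threshold = config$fpkm_filter)
  emit(dosage, "dosage_test.tsv", "dosage_correlation",
       paste0("genotypes = ", paste(unique(design$genotype), collapse = ",")),
       paste0("FDR = ", config$fdr))
  logf("dosage test: %d genes (%d testable)", nrow(dosage),
       sum(dosage$testable))

  ## stage: differential expression per contrast
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, design, sf = sf)
  de_list <- list()
  for (ct in config$contrasts) {
    lab <- paste0(ct[1], "_vs_", ct[2])
    genes_ct <- filter_expressed(fpkm, design, config$fpkm_filter, ct)
    de <- nb_wald_test(counts, design, group1 = ct[2], group2 = ct[1],
                       genes = genes_ct, sf = sf, dispersions = disp,
                       alpha_fdr = config$fdr)
    de_list[[lab]] <- de
    emit(de, paste0("de_", gsub("[^A-Za-z0-9_]", "", lab), ".tsv"),
         "differential_expression",
         paste0("contrast = ", lab, " (LFC > 0 = up in ", ct[1], ")"),
         paste0("FDR = ", config$fdr))
    logf("DE %s: %d tested, %d DTGs", lab, sum(!is.na(de$padj)), sum(de$dtg))
  }
  emit(dtg_table(de_list, ann), "dtg_by_chromosome.tsv", "report",
       "DTG counts per chromosome, Down/Up rows")

  ## stage: triads
  texpr <- triad_expression(fpkm, ds$triads, design,
                            euploid = config$euploid,
                            threshold = config$triad_threshold)
  logf("triads: %d expressed + %d unexpressed = %d",
       sum(texpr$expressed), sum(!texpr$expressed), nrow(ds$triads))
  eu_contrib <- texpr$contributions[
    texpr$contributions$genotype == config$euploid, ]
  ok <- stats::complete.cases(eu_contrib[c("a", "b", "d")]) &
    texpr$expressed[eu_contrib$triad_id]
  classes <- tibble::tibble(triad_id = eu_contrib$triad_id[ok])
  classes <- dplyr::bind_cols(classes, classify_bias(
    eu_contrib$a[ok], eu_contrib$b[ok], eu_contrib$d[ok]),
    ternary_coords(eu_contrib$a[ok], eu_contrib$b[ok], eu_contrib$d[ok]))
  emit(dplyr::bind_cols(classes,
                        eu_contrib[ok, c("a", "b", "d")]),
       "triad_class.tsv", "triad_analysis",
       paste0("euploid contributions; centroids per seven-category scheme"))
  emit(texpr$contributions, "triads_expr.tsv", "triad_analysis",
       paste0("summed FPKM; expressed if euploid total > ",
              config$triad_threshold))
  if (config$plots) {
    ggplot2::ggsave(file.path(config$out_dir, "ternary_euploid.pdf"),
                    plot_ternary(dplyr::bind_cols(
                      eu_contrib[ok, c("a", "b", "d")],
                      classes["category"])), width = 7, height = 6.5)
  }

  ## per-contrast triad ANOVA + buffering summaries
  buffering <- list(); dtts <- list()
  for (ct in config$contrasts) {
    lab <- paste0(ct[1], "_vs_", ct[2])
    dtt <- dtt_test(texpr, genotypes = ct, alpha_fdr = config$fdr)
    dtts[[lab]] <- dtt
    emit(dtt, paste0("dtt_", gsub("[^A-Za-z0-9_]", "", lab), ".tsv"),
         "triad_analysis", paste0("one-way ANOVA on triad totals, ", lab),
         paste0("FDR = ", config$fdr))
    vspec <- varied_region(config$karyotypes[[ct[1]]],
                           config$karyotypes[[ct[2]]])
    if (!is.null(vspec)) {
      rep_ <- tryCatch(
        buffering_report(texpr, de_list[[lab]], dtt, ann,
                         chromosome = vspec$chromosome,
                         start = vspec$start, end = vspec$end,
                         euploid = config$euploid),
        error = function(e) NULL)
      if (!is.null(rep_)) {
        buffering[[lab]] <- rep_
        logf("buffering %s: %d triads, DTG %.1f%%, DTT %.1f%%", lab,
             rep_$summary$n_expressed_triads,
             100 * rep_$summary$dtg_fraction, 100 * rep_$summary$dtt_fraction)
      }
    }
  }
  if (length(buffering)) {
    emit(dplyr::bind_rows(lapply(names(buffering), function(nm) {
      dplyr::mutate(buffering[[nm]]$summary, contrast = nm, .before = 1)
    })), "buffering_summary.tsv", "triad_analysis",
    "expressed triads on the varied chromosome/segment")
  }
  logf("pipeline complete: %s", normalizePath(config$out_dir))

  invisible(list(dataset = ds, fpkm = fpkm, genotype_means = gmeans,
                 qc = qc, expressed = expressed, profiles = profiles,
                 dosage = dosage, size_factors = sf, dispersions = disp,
                 de = de_list, triad_expression = texpr, classes = classes,
                 dtt = dtts, buffering = buffering))
}
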