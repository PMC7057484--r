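#' Configuration of the allohexaploid count simulator
#'
#' Collects every tunable of [simulate_dataset()] and validates it before any
#' sampling. The defaults emulate the aneuploid series the package analyses:
#' a 21-chromosome hexaploid genome at annotation scale, about half of the
#' genes organized into A/B/D homoeolog triads, negative-binomial counts with
#' moderate biological dispersion, and three field-grown biological
#' replicates per genotype.
#'
#' @param chromosomes chromosomes to simulate (default all 21, `"1A"`..`"7D"`).
#' @param genes_per_chromosome genes per chromosome: a scalar, or a named
#'   vector whose names are chromosome labels (unnamed chromosomes fall back
#'   to the scalar default of 5000, the approximate per-chromosome size of
#'   the full high-confidence wheat gene complement).
#' @param chromosome_length chromosome length in bp (default 600 Mb).
#' @param triad_fraction proportion of genes organized into triads, applied
#'   per homoeologous group (default 0.5; in wheat 55,422 of ~107k genes
#'   belong to triads).
#' @param responding_fraction proportion of genes whose expected expression
#'   scales with chromosome dosage; scalar or named per-chromosome vector.
#'   The count per chromosome is exact: `round(fraction * n_genes)` genes are
#'   drawn without replacement.
#' @param base_mean_meanlog,base_mean_sdlog log-normal law of the euploid
#'   expected count per gene (triad members share a triad-level draw, see
#'   `triad_member_sdlog`).
#' @param triad_member_sdlog log-normal spread of the three members of a
#'   triad around the triad-level base mean; 0 gives perfectly balanced
#'   triads. The default 0.35 reproduces the euploid ternary category mix
#'   of hexaploid wheat spikes, with about 60% of expressed triads
#'   classified balanced.
#' @param dispersion negative-binomial dispersion alpha (variance =
#'   mu + alpha * mu^2); 0 gives Poisson counts.
#' @param dispersion_sdlog optional log-normal spread of per-gene dispersions
#'   around `dispersion` (default 0: one shared alpha).
#' @param bio_noise_sdlog log-normal standard deviation of the per-replicate
#'   biological noise factor applied to every gene's expected mean. Members
#'   of a triad share one draw per sample (homoeologs see the same trans
#'   environment within a plant); other genes draw independently.
#' @param library_sdlog log-normal standard deviation of the per-sample
#'   library scaling factor.
#' @param replicates_per_genotype biological replicates per genotype
#'   (default 3).
#' @param length_meanlog,length_sdlog log-normal law of gene lengths (nt).
#' @param trans_effect_fraction proportion of genes, off the dosage-varied
#'   chromosomes, perturbed in aneuploid genotypes (default 0: no
#'   trans-effects).
#' @param trans_effect_meanlog,trans_effect_sdlog log-normal law of the
#'   trans-effect multiplier (default centred slightly below 1, matching the
#'   predominance of downregulation among trans-affected genes).
#' @param compensation coefficient in `[0, 1]` for active dosage
#'   compensation by sister homoeoalleles: 0 (default) is passive buffering,
#'   1 rescales the unaffected members of a cis-affected triad so that the
#'   triad's expected total equals its euploid total.
#' @param seed RNG seed; the whole dataset is reproducible given the seed.
#' @return A validated list of class `tb_sim_config`.
#' @export
simulation_config <- function(chromosomes = wheat_chromosomes(),
                              genes_per_chromosome = 5000,
                              chromosome_length = 600e6,
                              triad_fraction = 0.5,
                              responding_fraction = 0.85,
                              base_mean_meanlog = log(100),
                              base_mean_sdlog = 1.5,
                              triad_member_sdlog = 0.35,
                              dispersion = 0.05,
                              dispersion_sdlog = 0,
                              bio_noise_sdlog = 0.1,
                              library_sdlog = 0.1,
                              replicates_per_genotype = 3,
                              length_meanlog = log(1500),
                              length_sdlog = 0.5,
                              trans_effect_fraction = 0,
                              trans_effect_meanlog = log(0.9),
                              trans_effect_sdlog = 0.1,
                              compensation = 0,
                              seed = 1) {
  cfg <- list(chromosomes = chromosomes,
              genes_per_chromosome = genes_per_chromosome,
              chromosome_length = chromosome_length,
              triad_fraction = triad_fraction,
              responding_fraction = responding_fraction,
              base_mean_meanlog = base_mean_meanlog,
              base_mean_sdlog = base_mean_sdlog,
              triad_member_sdlog = triad_member_sdlog,
              dispersion = dispersion,
              dispersion_sdlog = dispersion_sdlog,
              bio_noise_sdlog = bio_noise_sdlog,
              library_sdlog = library_sdlog,
              replicates_per_genotype = replicates_per_genotype,
              length_meanlog = length_meanlog,
              length_sdlog = length_sdlog,
              trans_effect_fraction = trans_effect_fraction,
              trans_effect_meanlog = trans_effect_meanlog,
              trans_effect_sdlog = trans_effect_sdlog,
              compensation = compensation,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "tb_sim_config")
}

validate_sim_config <- function(cfg) {
  chk_prop <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop("invalid simulation config: ", nm, " must lie in [0, 1]")
    }
  }
  chk_prop(cfg$triad_fraction, "triad_fraction")
  chk_prop(cfg$responding_fraction, "responding_fraction")
  chk_prop(cfg$trans_effect_fraction, "trans_effect_fraction")
  chk_prop(cfg$compensation, "compensation")
  if (cfg$dispersion < 0) stop("invalid simulation config: dispersion must be >= 0")
  if (any(cfg$genes_per_chromosome < 1)) {
    stop("invalid simulation config: genes_per_chromosome must be >= 1")
  }
  if (cfg$replicates_per_genotype < 1) {
    stop("invalid simulation config: replicates_per_genotype must be >= 1")
  }
  if (cfg$chromosome_length <= 0) {
    stop("invalid simulation config: chromosome_length must be positive")
  }
  bad <- setdiff(cfg$chromosomes, wheat_chromosomes())
  if (length(bad)) {
    stop("invalid simulation config: unknown chromosome(s) ",
         paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

per_chromosome <- function(x, chromosomes, default) {
  if (is.null(names(x))) {
    if (length(x) != 1) stop("unnamed per-chromosome value must be a scalar")
    return(stats::setNames(rep(x, length(chromosomes)), chromosomes))
  }
  out <- stats::setNames(rep(default, length(chromosomes)), chromosomes)
  known <- intersect(names(x), chromosomes)
  out[known] <- x[known]
  out
}

#' Expected count mean under a gene-dosage model
#'
#' The dosage-response law of the simulator: a responding gene's expected
#' count scales linearly with its copy number relative to the disomic state
#' (`base_mean * dosage / 2`), while a non-responding gene keeps its euploid
#' mean regardless of dosage.
#'
#' @param base_mean euploid expected count (>= 0).
#' @param dosage chromosome copy number at the gene (>= 0).
#' @param responding logical; does the gene respond to dosage?
#' @return Expected count mean(s); vectorized over all arguments.
#' @export
expected_mean <- function(base_mean, dosage, responding) {
  stopifnot(all(base_mean >= 0), all(dosage >= 0))
  n <- max(length(base_mean), length(dosage), length(responding))
  base_mean <- rep_len(base_mean, n)
  dosage <- rep_len(dosage, n)
  responding <- rep_len(responding, n)
  ifelse(responding, base_mean * dosage / 2, base_mean)
}

#' Expected means for all genes and genotypes, with homoeolog compensation
#'
#' Applies [expected_mean()] per gene and genotype and then, for triads with
#' a cis-affected responding member, rescales the sister homoeoalleles (the
#' members whose own copy number is unchanged) by
#' `1 + compensation * deficit / sister_total`, where `deficit` is the
#' triad's expected-total loss (or, negative, gain) relative to the euploid.
#' At `compensation = 1` the triad's expected total is restored exactly to
#' its euploid value; at 0 buffering is purely passive.
#'
#' @param annotation a [gene_annotation()] tibble.
#' @param base_mean named numeric vector of euploid means (names = gene ids).
#' @param responding named logical vector (names = gene ids).
#' @param karyotypes named list of [karyotype()] objects.
#' @param triads optional [triad_catalog()]; needed only when
#'   `compensation > 0`.
#' @param compensation coefficient in `[0, 1]`.
#' @return Matrix of expected means, genes x genotypes.
#' @export
expected_means <- function(annotation, base_mean, responding, karyotypes,
                           triads = NULL, compensation = 0) {
  genes <- annotation$gene_id
  base_mean <- base_mean[genes]
  responding <- responding[genes]
  mu <- matrix(NA_real_, nrow = length(genes), ncol = length(karyotypes),
               dimnames = list(genes, names(karyotypes)))
  triad_of <- NULL
  if (!is.null(triads) && nrow(triads)) {
    triad_of <- stats::setNames(
      rep(triads$triad_id, 3), c(triads$A, triads$B, triads$D))[genes]
  }
  for (g in names(karyotypes)) {
    kt <- karyotypes[[g]]
    dose <- dosage_of(kt, annotation)
    m <- expected_mean(base_mean, dose, responding)
    if (compensation > 0 && !is.null(triad_of)) {
      in_triad <- !is.na(triad_of)
      affected <- in_triad & responding & dose != kt$baseline_copy
      if (any(affected)) {
        tid <- triad_of[in_triad]
        deficit <- rowsum(ifelse(affected[in_triad],
                                 base_mean[in_triad] - m[in_triad], 0), tid)
        sister <- in_triad & dose == kt$baseline_copy
        sister_tot <- rowsum(ifelse(sister[in_triad], m[in_triad], 0), tid)
        fac <- stats::setNames(rep(1, nrow(deficit)), rownames(deficit))
        ok <- sister_tot[, 1] > 0 & deficit[, 1] != 0
        fac[ok] <- pmax(0, 1 + compensation * deficit[ok, 1] / sister_tot[ok, 1])
        m[sister] <- m[sister] * fac[triad_of[sister]]
      }
    }
    mu[, g] <- m
  }
  mu
}

#' Simulate an allohexaploid RNA-seq count dataset
#'
#' Builds a hexaploid genome (gene positions uniform along each chromosome,
#' triads occupying homologous relative positions across the three
#' subgenomes of a homoeologous group), assigns log-normal base means and
#' dosage-responding flags, derives per-genotype expected means from the
#' karyotypes via [expected_means()], and draws negative-binomial counts
#'
#' \deqn{K_{gj} \sim NB(\mu = s_j b_{gj} \mu_{g,geno(j)},\ Var = \mu + \alpha_g \mu^2)}
#'
#' where `s_j` is the sample library factor and `b_{gj}` the per-replicate
#' biological noise factor (shared among the members of a triad within a
#' sample). The dataset is bit-reproducible given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param karyotypes named list of [karyotype()] objects; must contain one
#'   named `"euploid"`.
#' @return A list of class `tb_dataset` with elements `counts` (genes x
#'   samples integer matrix), `annotation`, `triads`, `design`, `karyotypes`,
#'   `truth` (per gene: responding flag, triad id, base mean, per-genotype
#'   dosage and expected mean, trans multipliers) and `config`.
#' @export
simulate_dataset <- function(config, karyotypes = wheat_karyotypes()) {
  validate_sim_config(config)
  if (!"euploid" %in% names(karyotypes)) {
    stop("karyotypes must include one named \"euploid\"")
  }
  set.seed(config$seed)
  chroms <- config$chromosomes
  n_chr <- per_chromosome(config$genes_per_chromosome, chroms, 5000)
  resp_frac <- per_chromosome(config$responding_fraction, chroms,
                              if (is.null(names(config$responding_fraction)))
                                config$responding_fraction[1] else 0.85)

  ## --- genome: triads first (homologous relative positions), then singletons
  groups <- sort(unique(substr(chroms, 1, 1)))
  ann_rows <- list(); triad_rows <- list()
  triad_of <- character(0)
  for (grp in groups) {
    trio <- paste0(grp, c("A", "B", "D"))
    present <- trio[trio %in% chroms]
    n_tri <- if (length(present) == 3) {
      round(config$triad_fraction * min(n_chr[present]))
    } else 0L
    if (n_tri > 0) {
      rel <- stats::runif(n_tri)
      tid <- sprintf("T%s_%05d", grp, seq_len(n_tri))
      member_ids <- list()
      for (chr in present) {
        gid <- sprintf("G%s_%05d", chr, seq_len(n_tri))
        member_ids[[substr(chr, 2, 2)]] <- gid
        ann_rows[[chr]] <- tibble::tibble(gene_id = gid, chromosome = chr,
                                          rel_pos = rel)
        triad_of[gid] <- tid
      }
      triad_rows[[grp]] <- tibble::tibble(
        triad_id = tid, A = member_ids$A, B = member_ids$B, D = member_ids$D,
        syntenic = TRUE)
    }
    for (chr in present) {
      n_single <- n_chr[chr] - if (n_tri > 0) n_tri else 0L
      if (n_single > 0) {
        gid <- sprintf("G%s_%05d", chr, n_tri + seq_len(n_single))
        ann_rows[[paste0(chr, "_s")]] <- tibble::tibble(
          gene_id = gid, chromosome = chr, rel_pos = stats::runif(n_single))
      }
    }
  }
  pos_tab <- dplyr::bind_rows(ann_rows)
  lengths <- pmax(200, round(stats::rlnorm(nrow(pos_tab), config$length_meanlog,
                                           config$length_sdlog)))
  start <- round(pos_tab$rel_pos * (config$chromosome_length - max(lengths) - 1))
  annotation <- gene_annotation(pos_tab$gene_id, pos_tab$chromosome,
                                start, start + lengths)
  triads <- if (length(triad_rows)) dplyr::bind_rows(triad_rows) else
    triad_catalog(character(0), character(0), character(0), character(0))
  genes <- annotation$gene_id
  n_genes <- nrow(annotation)

  ## --- base means: triad-level draw shared by members, log-normal member spread
  tid_all <- triad_of[genes]
  base_mean <- stats::rlnorm(n_genes, config$base_mean_meanlog,
                             config$base_mean_sdlog)
  if (nrow(triads)) {
    tri_mean <- stats::setNames(
      stats::rlnorm(nrow(triads), config$base_mean_meanlog, config$base_mean_sdlog),
      triads$triad_id)
    in_tri <- !is.na(tid_all)
    member_dev <- if (config$triad_member_sdlog > 0) {
      stats::rlnorm(sum(in_tri), 0, config$triad_member_sdlog)
    } else 1
    base_mean[in_tri] <- tri_mean[tid_all[in_tri]] * member_dev
  }
  names(base_mean) <- genes

  ## --- responding flags: exact count per chromosome
  responding <- logical(n_genes)
  for (chr in chroms) {
    idx <- which(annotation$chromosome == chr)
    k <- round(resp_frac[chr] * length(idx))
    if (k > 0) responding[idx[sample.int(length(idx), k)]] <- TRUE
  }
  names(responding) <- genes

  ## --- expected means per genotype (dosage response + compensation)
  mu <- expected_means(annotation, base_mean, responding, karyotypes,
                       triads = triads, compensation = config$compensation)

  ## --- trans effects on unvaried chromosomes of aneuploid genotypes
  trans_mult <- matrix(1, n_genes, length(karyotypes),
                       dimnames = list(genes, names(karyotypes)))
  if (config$trans_effect_fraction > 0) {
    n_trans <- round(config$trans_effect_fraction * n_genes)
    trans_genes <- sample(n_genes, n_trans)
    for (g in names(karyotypes)) {
      kt <- karyotypes[[g]]
      if (!nrow(kt$overrides)) next
      dose <- dosage_of(kt, annotation)
      hit <- intersect(trans_genes, which(dose == kt$baseline_copy))
      trans_mult[hit, g] <- stats::rlnorm(length(hit), config$trans_effect_meanlog,
                                          config$trans_effect_sdlog)
    }
    mu <- mu * trans_mult
  }

  ## --- design and sampling
  genos <- names(karyotypes)
  design <- sample_design(
    sample_id = paste0(rep(genos, each = config$replicates_per_genotype), "_r",
                       rep(seq_len(config$replicates_per_genotype), length(genos))),
    genotype_name = rep(genos, each = config$replicates_per_genotype),
    replicate_index = rep(seq_len(config$replicates_per_genotype), length(genos)))
  n_samp <- nrow(design)
  lib <- stats::rlnorm(n_samp, 0, config$library_sdlog)

  alpha <- if (config$dispersion_sdlog > 0 && config$dispersion > 0) {
    stats::rlnorm(n_genes, log(config$dispersion), config$dispersion_sdlog)
  } else rep(config$dispersion, n_genes)

  counts <- matrix(0L, n_genes, n_samp, dimnames = list(genes, design$sample))
  in_tri <- !is.na(tid_all)
  tri_index <- match(tid_all, triads$triad_id)
  for (j in seq_len(n_samp)) {
    bio <- stats::rlnorm(n_genes, 0, config$bio_noise_sdlog)
    if (config$bio_noise_sdlog > 0 && nrow(triads)) {
      tri_bio <- stats::rlnorm(nrow(triads), 0, config$bio_noise_sdlog)
      bio[in_tri] <- tri_bio[tri_index[in_tri]]
    }
    mu_j <- lib[j] * bio * mu[, design$genotype[j]]
    counts[, j] <- draw_nb(mu_j, alpha)
  }

  truth <- tibble::tibble(
    gene_id = genes,
    chromosome = annotation$chromosome,
    position = gene_midpoint(annotation),
    triad_id = ifelse(is.na(tid_all), NA_character_, tid_all),
    base_mean = unname(base_mean),
    responding = unname(responding),
    dispersion = alpha)
  for (g in genos) {
    truth[[paste0("dosage_", g)]] <- dosage_of(karyotypes[[g]], annotation)
    truth[[paste0("mu_", g)]] <- unname(mu[, g])
    if (config$trans_effect_fraction > 0) {
      truth[[paste0("trans_", g)]] <- unname(trans_mult[, g])
    }
  }

  structure(list(counts = counts, annotation = annotation, triads = triads,
                 design = design, karyotypes = karyotypes, truth = truth,
                 library_factors = stats::setNames(lib, design$sample),
                 config = config),
            class = "tb_dataset")
}

# NB sampler with Poisson limit at alpha = 0 (per-gene alpha vector).
draw_nb <- function(mu, alpha) {
  out <- integer(length(mu))
  pois <- alpha <= 0
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    out[!pois] <- stats::rnbinom(sum(!pois), size = 1 / alpha[!pois],
                                 mu = mu[!pois])
  }
  out
}

#' @export
print.tb_dataset <- function(x, ...) {
  cat("<tb_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples; ", nrow(x$triads), " triads; genotypes: ",
      paste(names(x$karyotypes), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Emits the files every downstream reader consumes: `counts.tsv`,
#' `annotation.tsv` (plus `annotation.gff3`), `triads.tsv`, `design.tsv`,
#' `karyotypes.tsv`, `truth.tsv` and `config.yaml`.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(dataset$counts, file.path(dir, "counts.tsv"))
  write_annotation(dataset$annotation, file.path(dir, "annotation.tsv"), "tsv")
  write_annotation(dataset$annotation, file.path(dir, "annotation.gff3"), "gff3")
  write_triads(dataset$triads, file.path(dir, "triads.tsv"))
  write_design(dataset$design, file.path(dir, "design.tsv"))
  write_karyotypes(dataset$karyotypes, file.path(dir, "karyotypes.tsv"))
  readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  yaml::write_yaml(unclass(dataset$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read / write a gene count matrix
#'
#' TSV with a `gene_id` column followed by one column per sample.
#'
#' @param path file path.
#' @return `read_counts()`: integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  tab <- read_tsv_strict(path, "gene_id")
  m <- as.matrix(tab[setdiff(names(tab), "gene_id")])
  rownames(m) <- tab$gene_id
  storage.mode(m) <- "double"
  m
}

#' @param counts genes x samples matrix with dimnames.
#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(gene_id = rownames(counts)),
                                    tibble::as_tibble(counts)), path)
  invisible(path)
}
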