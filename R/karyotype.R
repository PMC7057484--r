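#' Karyotypes: per-genotype chromosome copy numbers
#'
#' A karyotype maps every gene position to a copy number. It consists of a
#' baseline copy number (2 for a disomic hexaploid) plus a list of overrides,
#' each covering a whole chromosome or an interval of one. A monosomic line
#' overrides one chromosome to 1 copy, a trisomic line to 3, a nullisomic
#' line to 0, and a segmental tetrasomic line overrides an interval to 4.
#'
#' @param genotype_name name of the genotype carrying this karyotype.
#' @param baseline_copy copy number of every unlisted chromosome (default 2).
#' @param overrides a data frame with columns `chromosome`, `start`, `end`
#'   (0-based half-open; `NA` start/end = whole chromosome) and `copies`
#'   (integer >= 0). Overrides must not overlap on the same chromosome.
#' @return An object of class `tb_karyotype`.
#' @export
karyotype <- function(genotype_name, baseline_copy = 2, overrides = NULL) {
  if (is.null(overrides)) {
    overrides <- tibble::tibble(chromosome = character(), start = numeric(),
                                end = numeric(), copies = numeric())
  }
  overrides <- tibble::as_tibble(overrides)
  need <- c("chromosome", "copies")
  stopifnot(all(need %in% names(overrides)))
  if (!"start" %in% names(overrides)) overrides$start <- NA_real_
  if (!"end" %in% names(overrides)) overrides$end <- NA_real_
  overrides <- overrides[c("chromosome", "start", "end", "copies")]
  if (any(overrides$copies < 0)) stop("copy numbers must be >= 0")
  if (baseline_copy < 0) stop("baseline_copy must be >= 0")
  # overlap check per chromosome (whole-chromosome override counts as covering
  # everything on it)
  for (chr in unique(overrides$chromosome)) {
    o <- overrides[overrides$chromosome == chr, ]
    if (nrow(o) > 1) {
      s <- ifelse(is.na(o$start), -Inf, o$start)
      e <- ifelse(is.na(o$end), Inf, o$end)
      ord <- order(s)
      if (any(s[ord][-1] < e[ord][-nrow(o)])) {
        stop("overlapping karyotype overrides on chromosome ", chr,
             " for genotype ", genotype_name)
      }
    }
  }
  structure(list(genotype_name = genotype_name,
                 baseline_copy = baseline_copy,
                 overrides = overrides),
            class = "tb_karyotype")
}

#' @export
print.tb_karyotype <- function(x, ...) {
  cat("<karyotype> ", x$genotype_name, ": baseline ", x$baseline_copy,
      " copies", sep = "")
  if (nrow(x$overrides)) {
    cat("; overrides:\n")
    print(as.data.frame(x$overrides))
  } else cat(" (euploid)\n")
  invisible(x)
}

#' Copy number at each gene
#'
#' Looks up the chromosome copy number carried by `karyotype` at every gene of
#' `annotation`. A gene falls under an interval override when its midpoint
#' lies inside the (0-based half-open) interval; a whole-chromosome override
#' applies to every gene on that chromosome; everything else takes the
#' baseline copy number. The midpoint rule makes the assignment of
#' boundary-straddling genes deterministic and order-free.
#'
#' @param karyotype a [karyotype()] object.
#' @param annotation a [gene_annotation()] tibble (any number of genes).
#' @return Integer-valued numeric vector of copy numbers, one per gene.
#' @export
dosage_of <- function(karyotype, annotation) {
  stopifnot(inherits(karyotype, "tb_karyotype"))
  dose <- rep(karyotype$baseline_copy, nrow(annotation))
  if (!nrow(karyotype$overrides)) return(dose)
  mid <- gene_midpoint(annotation)
  ov <- karyotype$overrides
  for (i in seq_len(nrow(ov))) {
    on_chr <- annotation$chromosome == ov$chromosome[i]
    if (is.na(ov$start[i]) || is.na(ov$end[i])) {
      hit <- on_chr
    } else {
      hit <- on_chr & mid >= ov$start[i] & mid < ov$end[i]
    }
    dose[hit] <- ov$copies[i]
  }
  dose
}

#' The five study karyotypes
#'
#' Returns the karyotypes of the aneuploid series analysed by the package:
#' the euploid (2n = 42, all chromosomes disomic), M4B (monosomic 4B, 1
#' copy), Tri4B (trisomic 4B, 3 copies), SegT2A (a segment of chromosome arm
#' 2AS carried at 4 copies) and N7B+SegT2A (nullisomic 7B combined with the
#' same 2AS segmental tetrasomy).
#'
#' @param segment_2AS numeric length-2 vector, the 0-based half-open interval
#'   of the duplicated 2AS segment. The default covers the first 30% of a
#'   600 Mb chromosome 2A, the approximate share of 2A genes the segment
#'   carries.
#' @return Named list of [karyotype()] objects.
#' @export
wheat_karyotypes <- function(segment_2AS = c(0, 180e6)) {
  seg <- tibble::tibble(chromosome = "2A", start = segment_2AS[1],
                        end = segment_2AS[2], copies = 4)
  list(
    euploid = karyotype("euploid"),
    M4B = karyotype("M4B", overrides = tibble::tibble(
      chromosome = "4B", start = NA_real_, end = NA_real_, copies = 1)),
    Tri4B = karyotype("Tri4B", overrides = tibble::tibble(
      chromosome = "4B", start = NA_real_, end = NA_real_, copies = 3)),
    SegT2A = karyotype("SegT2A", overrides = seg),
    `N7B+SegT2A` = karyotype("N7B+SegT2A", overrides = dplyr::bind_rows(
      seg, tibble::tibble(chromosome = "7B", start = NA_real_,
                          end = NA_real_, copies = 0)))
  )
}

#' Read / write karyotype tables
#'
#' TSV with header `genotype`, `chromosome`, `start`, `end`, `copies`. Empty
#' `start`/`end` mean a whole-chromosome override; a row with chromosome
#' `"*"` sets the genotype's baseline copy number (absent rows leave it at
#' 2).
#'
#' @param path file path.
#' @return `read_karyotypes()`: a named list of [karyotype()] objects.
#' @export
read_karyotypes <- function(path) {
  tab <- read_tsv_strict(path, c("genotype", "chromosome", "copies"))
  if (!"start" %in% names(tab)) tab$start <- NA_real_
  if (!"end" %in% names(tab)) tab$end <- NA_real_
  out <- lapply(split(tab, tab$genotype), function(g) {
    base <- g$copies[g$chromosome == "*"]
    ov <- g[g$chromosome != "*", c("chromosome", "start", "end", "copies")]
    karyotype(g$genotype[1],
              baseline_copy = if (length(base)) base[1] else 2,
              overrides = ov)
  })
  out[unique(tab$genotype)]
}

#' @param karyotypes a named list of [karyotype()] objects.
#' @rdname read_karyotypes
#' @export
write_karyotypes <- function(karyotypes, path) {
  rows <- lapply(karyotypes, function(k) {
    base <- tibble::tibble(genotype = k$genotype_name, chromosome = "*",
                           start = NA_real_, end = NA_real_,
                           copies = k$baseline_copy)
    if (nrow(k$overrides)) {
      dplyr::bind_rows(base, dplyr::mutate(k$overrides,
                                           genotype = k$genotype_name,
                                           .before = 1))
    } else base
  })
  readr::write_tsv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' Sample design tables
#'
#' The design maps each RNA-seq sample to its genotype and biological
#' replicate index. Variance-based stages (replicate correlation, the NB Wald
#' test, the triad ANOVA) need at least 2 replicates per genotype.
#'
#' @param sample_id,genotype_name,replicate_index parallel vectors.
#' @return A tibble with columns `sample`, `genotype`, `replicate`.
#' @export
sample_design <- function(sample_id, genotype_name, replicate_index) {
  stopifnot(length(sample_id) == length(genotype_name),
            length(sample_id) == length(replicate_index))
  if (anyDuplicated(sample_id)) stop("duplicated sample ids in design")
  tibble::tibble(sample = as.character(sample_id),
                 genotype = as.character(genotype_name),
                 replicate = as.integer(replicate_index))
}

#' @param path file path (TSV with header `sample`, `genotype`, `replicate`).
#' @rdname sample_design
#' @export
read_design <- function(path) {
  tab <- read_tsv_strict(path, c("sample", "genotype", "replicate"))
  sample_design(tab$sample, tab$genotype, tab$replicate)
}

#' @param design a [sample_design()] tibble.
#' @rdname sample_design
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' Triad catalogues
#'
#' A triad is a set of three homoeologous gene copies, one per subgenome
#' (A, B, D). The catalogue drives the buffering analysis; no gene may belong
#' to two triads and, when an annotation is supplied, each member must map to
#' its subgenome.
#'
#' @param triad_id,gene_a,gene_b,gene_d parallel vectors of ids.
#' @param syntenic logical flag per triad (nonsyntenic triads are carried
#'   through with the flag only).
#' @param annotation optional [gene_annotation()] used to check that members
#'   lie on the A/B/D subgenomes respectively.
#' @return A tibble with columns `triad_id`, `A`, `B`, `D`, `syntenic`.
#' @export
triad_catalog <- function(triad_id, gene_a, gene_b, gene_d, syntenic = TRUE,
                          annotation = NULL) {
  tab <- tibble::tibble(triad_id = as.character(triad_id),
                        A = as.character(gene_a), B = as.character(gene_b),
                        D = as.character(gene_d),
                        syntenic = rep_len(as.logical(syntenic), length(triad_id)))
  members <- c(tab$A, tab$B, tab$D)
  if (anyDuplicated(members)) {
    stop("gene(s) assigned to more than one triad: ",
         paste(utils::head(unique(members[duplicated(members)]), 3), collapse = ", "))
  }
  if (!is.null(annotation)) {
    sg <- stats::setNames(annotation$subgenome, annotation$gene_id)
    for (col in c("A", "B", "D")) {
      got <- sg[tab[[col]]]
      bad <- !is.na(got) & got != col & got != "unknown"
      if (any(bad)) {
        stop("triad ", tab$triad_id[which(bad)[1]], ": gene ",
             tab[[col]][which(bad)[1]], " is not on subgenome ", col)
      }
    }
  }
  tab
}

#' @param path file path (TSV with header `triad_id`, `A`, `B`, `D`,
#'   optional `syntenic`).
#' @rdname triad_catalog
#' @export
read_triads <- function(path) {
  tab <- read_tsv_strict(path, c("triad_id", "A", "B", "D"))
  triad_catalog(tab$triad_id, tab$A, tab$B, tab$D,
                syntenic = if ("syntenic" %in% names(tab)) tab$syntenic else TRUE)
}

#' @param triads a [triad_catalog()] tibble.
#' @rdname triad_catalog
#' @export
write_triads <- function(triads, path) {
  readr::write_tsv(triads, path)
  invisible(path)
}
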