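#' Gene annotation tables
#'
#' A gene annotation is a tibble with one row per gene and columns
#' `gene_id`, `chromosome` (one of `"1A"`..`"7D"` or `"Un"`), `start`, `end`
#' (internal 0-based half-open coordinates), `length` (`end - start`, nt) and
#' `subgenome` (`"A"`, `"B"`, `"D"` or `"unknown"`). It is the coordinate
#' backbone of the chromosome ratio profiles and of every karyotype dosage
#' lookup.
#'
#' Coordinate conventions: internally all intervals are 0-based half-open.
#' GFF3 input/output is 1-based inclusive, BED and the plain TSV dialect are
#' 0-based half-open; conversion happens at the file boundary and nowhere
#' else.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chromosome chromosome labels (`"1A"`..`"7D"`, `"Un"`).
#' @param start,end 0-based half-open interval per gene; `end > start`.
#' @param strand optional strand; parsed from files but ignored by every
#'   analysis step (nothing downstream is strand-dependent).
#' @return A tibble of class `tb_annotation`.
#' @export
gene_annotation <- function(gene_id, chromosome, start, end, strand = NULL) {
  stopifnot(length(gene_id) == length(chromosome),
            length(start) == length(end),
            length(gene_id) == length(start))
  if (anyDuplicated(gene_id)) {
    stop("duplicated gene_id in annotation: ",
         paste(utils::head(unique(gene_id[duplicated(gene_id)]), 3), collapse = ", "))
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    stop("gene ", gene_id[bad], " has non-positive length (start ", start[bad],
         ", end ", end[bad], ")")
  }
  chromosome <- as.character(chromosome)
  ann <- tibble::tibble(
    gene_id = as.character(gene_id),
    chromosome = chromosome,
    start = start,
    end = end,
    length = end - start,
    subgenome = subgenome_of(chromosome),
    strand = if (is.null(strand)) "." else as.character(strand)
  )
  unknown <- setdiff(unique(chromosome), c(wheat_chromosomes(), "Un"))
  if (length(unknown)) {
    warning("unknown chromosome label(s) ", paste(unknown, collapse = ", "),
            "; records kept with subgenome = \"unknown\"", call. = FALSE)
  }
  class(ann) <- c("tb_annotation", class(ann))
  ann
}

#' The 21 chromosomes of allohexaploid wheat
#'
#' @return Character vector `"1A"`, `"1B"`, `"1D"`, ..., `"7D"`.
#' @export
wheat_chromosomes <- function() {
  paste0(rep(1:7, each = 3), rep(c("A", "B", "D"), 7))
}

#' Subgenome of a chromosome label
#'
#' The trailing letter of a `"1A"`-style label names the subgenome;
#' `"Un"` (unassigned scaffolds) and anything unrecognized map to
#' `"unknown"`.
#'
#' @param chromosome character vector of chromosome labels.
#' @return Character vector over `"A"`, `"B"`, `"D"`, `"unknown"`.
#' @export
subgenome_of <- function(chromosome) {
  sg <- ifelse(grepl("^[1-7][ABD]$", chromosome),
               substr(chromosome, 2, 2), "unknown")
  sg
}

#' Gene midpoint
#'
#' Single x-coordinate per gene for profile plots and segment-dosage lookup.
#'
#' @param annotation a [gene_annotation()] tibble.
#' @return Numeric vector of interval midpoints (bp).
#' @export
gene_midpoint <- function(annotation) {
  (annotation$start + annotation$end) / 2
}

#' Read a gene annotation file
#'
#' Supports GFF3 (1-based inclusive, converted on read; parsed through
#' rtracklayer), BED (already 0-based half-open) and a plain TSV dialect with
#' header columns `gene_id`, `chromosome`, `start`, `end` (0-based half-open)
#' and optional `strand`.
#'
#' Records on chromosomes outside `"1A"`..`"7D"`/`"Un"` are kept with
#' `subgenome = "unknown"` and a warning; malformed lines raise an error
#' naming the offending line.
#'
#' @param path file path.
#' @param format `"gff3"`, `"bed"` or `"tsv"`; default guessed from the file
#'   extension.
#' @return A [gene_annotation()] tibble.
#' @export
read_annotation <- function(path, format = c("guess", "gff3", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gff = , gff3 = "gff3", bed = "bed", "tsv")
  }
  if (!file.exists(path)) stop("annotation file not found: ", path)
  switch(format,
    gff3 = read_annotation_gff3(path),
    bed  = read_annotation_bed(path),
    tsv  = read_annotation_tsv(path)
  )
}

read_annotation_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  gr <- gr[gr$type %in% c("gene") | is.na(gr$type)]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  if (anyNA(ids)) stop("GFF3 gene records without an ID attribute in ", path)
  gene_annotation(
    gene_id = ids,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,   # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

read_annotation_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) {
    stop("BED parse error in ", path, " at line ", which(nf < 4)[1],
         ": expected at least 4 tab-separated fields")
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    stop("BED parse error in ", path, " at line ",
         which(is.na(start) | is.na(end))[1], ": non-numeric coordinates")
  }
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6, length(f))], ""), ".")
  gene_annotation(
    gene_id = vapply(fields, `[[`, "", 4),
    chromosome = vapply(fields, `[[`, "", 1),
    start = start, end = end, strand = strand
  )
}

read_annotation_tsv <- function(path) {
  tab <- read_tsv_strict(path, c("gene_id", "chromosome", "start", "end"))
  gene_annotation(
    gene_id = tab$gene_id,
    chromosome = tab$chromosome,
    start = as.numeric(tab$start),
    end = as.numeric(tab$end),
    strand = if ("strand" %in% names(tab)) tab$strand else NULL
  )
}

#' Write a gene annotation file
#'
#' Inverse of [read_annotation()] for each dialect; a write/read round trip
#' reproduces the records.
#'
#' @param annotation a [gene_annotation()] tibble.
#' @param path output path.
#' @param format `"gff3"`, `"bed"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, format = c("tsv", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(annotation[c("gene_id", "chromosome", "start", "end", "strand")],
                     path)
  } else if (format == "bed") {
    bed <- data.frame(annotation$chromosome, format_bp(annotation$start),
                      format_bp(annotation$end), annotation$gene_id, 0L,
                      ifelse(annotation$strand %in% c("+", "-"), annotation$strand, "."))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    lines <- paste(annotation$chromosome, "triadbuffer", "gene",
                   format_bp(annotation$start + 1), format_bp(annotation$end),
                   ".", ifelse(annotation$strand %in% c("+", "-"), annotation$strand, "."),
                   ".", paste0("ID=", annotation$gene_id), sep = "\t")
    writeLines(c("##gff-version 3", lines), path)
  }
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

# Strict TSV reader used by all table loaders: checks required header columns
# and reports the first malformed line.
read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  probs <- readr::problems(tab)
  if (nrow(probs)) {
    stop("parse error in ", path, " at line ", probs$row[1] + 1, ": ",
         probs$expected[1], " expected", call. = FALSE)
  }
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  tab
}
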