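#' Construct a gene catalog
#'
#' A gene catalog is the ordered gene axis of the whole analysis: one row per
#' gene, sorted by (chromosome, start), with 0-based half-open coordinates and
#' a declared length for every chromosome. All downstream structures (windows,
#' indicator matrices, hotspots) index into this order.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open; `start < end`).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp, or
#'   `NULL` to infer each length as the maximum gene end on that chromosome
#'   (the inference is reported via `message()`).
#' @return A `gene_catalog`: a data.frame sorted by (chrom, start) with
#'   attributes `chrom_lengths` and `rejected` (genes dropped because their
#'   chromosome was not declared).
#' @details Exact duplicate records collapse to one entry; the same `gene_id`
#'   with conflicting coordinates is an error. When `chrom_lengths` is given
#'   explicitly, genes on undeclared chromosomes are rejected and reported.
#' @examples
#' cat <- gene_catalog(data.frame(
#'   gene_id = c("A", "B"), chrom = "chr1", start = c(100, 900), end = c(500, 1500)))
#' chrom_lengths(cat)
#' @export
gene_catalog <- function(genes, chrom_lengths = NULL) {
  need <- c("gene_id", "chrom", "start", "end")
  if (!is.data.frame(genes) || !all(need %in% names(genes)))
    stop("`genes` must be a data.frame with columns ", paste(need, collapse = ", "))
  genes <- data.frame(gene_id = as.character(genes$gene_id),
                      chrom = as.character(genes$chrom),
                      start = as.numeric(genes$start),
                      end = as.numeric(genes$end),
                      stringsAsFactors = FALSE)
  if (anyNA(genes))
    stop("gene catalog contains missing values")
  if (any(genes$start < 0))
    stop("gene start coordinates must be non-negative")
  bad <- genes$start >= genes$end
  if (any(bad))
    stop("start must be < end; offending gene(s): ",
         paste(utils::head(genes$gene_id[bad], 5L), collapse = ", "))

  genes <- unique(genes)
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup))
    stop("duplicate gene_id with conflicting coordinates: ",
         paste(utils::head(dup, 5L), collapse = ", "))

  rejected <- genes[0L, ]
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(genes$end, genes$chrom), max, numeric(1))
    message("chromosome lengths not supplied; inferred as max gene end for ",
            length(chrom_lengths), " chromosome(s)")
  } else {
    if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
      stop("`chrom_lengths` must be a named vector")
    chrom_lengths <- vapply(chrom_lengths, as.numeric, numeric(1))
    off <- !(genes$chrom %in% names(chrom_lengths))
    if (any(off)) {
      rejected <- genes[off, , drop = FALSE]
      message(sum(off), " gene(s) on undeclared chromosome(s) rejected: ",
              paste(unique(rejected$chrom), collapse = ", "))
      genes <- genes[!off, , drop = FALSE]
    }
  }
  if (nrow(genes) < 1L)
    stop("gene catalog must contain at least one gene")
  over <- genes$end > chrom_lengths[genes$chrom]
  if (any(over))
    stop("gene(s) extend beyond their declared chromosome length: ",
         paste(utils::head(genes$gene_id[over], 5L), collapse = ", "))

  genes <- genes[order(genes$chrom, genes$start, genes$end, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(genes,
            chrom_lengths = chrom_lengths[sort(names(chrom_lengths))],
            rejected = rejected,
            class = c("gene_catalog", "data.frame"))
}

#' Chromosome lengths of a catalog
#' @param catalog a [gene_catalog()].
#' @return Named numeric vector of lengths in bp.
#' @export
chrom_lengths <- function(catalog) attr(catalog, "chrom_lengths")

#' @export
print.gene_catalog <- function(x, ...) {
  cl <- chrom_lengths(x)
  cat("Gene catalog:", nrow(x), "genes on", length(cl), "chromosome(s)\n")
  cat("Total declared length:", format(sum(cl), big.mark = ","), "bp\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more gene(s)\n")
  invisible(x)
}

#' Read gene coordinates from BED or GTF
#'
#' BED intervals are taken as-is (BED is already 0-based half-open); GTF
#' records are converted from 1-based inclusive. Only `gene` features are kept
#' from a GTF. The result is a validated, sorted, deduplicated
#' [gene_catalog()].
#'
#' @param path file path.
#' @param format `"bed"` (columns chrom, start, end, name, ...) or `"gtf"`
#'   (requires the rtracklayer package).
#' @param chrom_lengths optional named numeric vector (see [gene_catalog()]),
#'   e.g. from [read_chromosome_lengths()].
#' @return A [gene_catalog()].
#' @export
read_gene_annotation <- function(path, format = c("bed", "gtf"),
                                 chrom_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  genes <- switch(format,
                  bed = .read_bed(path),
                  gtf = .read_gtf_genes(path))
  gene_catalog(genes, chrom_lengths)
}

.read_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no records in BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 4L
  if (any(short))
    stop("malformed BED line ", lineno[which(short)[1L]],
         ": expected at least 4 tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop("malformed BED line ", lineno[which(bad)[1L]],
         ": non-numeric coordinate")
  data.frame(gene_id = vapply(fields, `[[`, "", 4L),
             chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

.read_gtf_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF requires the 'rtracklayer' package")
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc)) gr <- gr[as.character(gr$type) == "gene"]
  if (!length(gr)) stop("no gene features in GTF file: ", path)
  if (!"gene_id" %in% names(S4Vectors::mcols(gr)))
    stop("GTF gene features carry no gene_id attribute")
  data.frame(gene_id = as.character(gr$gene_id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,  # 1-based inclusive -> 0-based half-open
             end = as.numeric(GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}

#' Read a two-column chromosome-lengths file
#' @param path tab-separated file: chromosome name, length in bp.
#' @return Named numeric vector.
#' @export
read_chromosome_lengths <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(tab) < 2L) stop("chromosome-lengths file needs two columns (name, length)")
  len <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(len)) stop("non-numeric chromosome length at line ", which(is.na(len))[1L])
  stats::setNames(len, tab[[1L]])
}

#' Write a gene catalog as BED4
#' @param catalog a [gene_catalog()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(catalog, path) {
  out <- sprintf("%s\t%s\t%s\t%s", catalog$chrom,
                 format(catalog$start, scientific = FALSE, trim = TRUE),
                 format(catalog$end, scientific = FALSE, trim = TRUE),
                 catalog$gene_id)
  writeLines(out, path)
  invisible(path)
}

#' Write chromosome lengths
#' @param lengths named numeric vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chromosome_lengths <- function(lengths, path) {
  writeLines(sprintf("%s\t%s", names(lengths),
                     format(lengths, scientific = FALSE, trim = TRUE)), path)
  invisible(path)
}
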