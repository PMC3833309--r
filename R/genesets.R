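#' Construct a gene-set collection against a catalog
#'
#' Members are intersected with the catalog; sets whose intersection falls
#' below `min_size` are dropped (the default reproduces the usual >= 15-gene
#' floor for GO term collections). Dropped sets and unknown member ids are
#' reported and retained as attributes.
#'
#' @param members named list of character vectors of gene ids; names are set ids.
#' @param namespace character vector (recycled) in `"BP"`, `"MF"`, `"CC"`,
#'   `"other"` — the GO namespace or `"other"` for non-GO collections.
#' @param catalog a [gene_catalog()].
#' @param min_size minimum post-intersection set size (default 15).
#' @return A `gene_sets` data.frame: `set_id`, `namespace`, `size`, and a
#'   `members` list-column of catalog gene ids; attributes `dropped` (set ids
#'   excluded by the size filter) and `n_unknown_members`.
#' @export
gene_sets <- function(members, namespace = "other", catalog, min_size = 15L) {
  if (!length(members)) stop("empty gene-set collection")
  if (is.null(names(members)) || any(!nzchar(names(members))))
    stop("`members` must be a named list")
  dupid <- unique(names(members)[duplicated(names(members))])
  if (length(dupid))
    stop("duplicate set_id: ", paste(utils::head(dupid, 5L), collapse = ", "))
  namespace <- rep_len(.norm_namespace(namespace), length(members))

  known <- catalog$gene_id
  clean <- lapply(members, function(m) unique(m[m %in% known]))
  n_unknown <- sum(lengths(lapply(members, unique))) - sum(lengths(clean))
  if (n_unknown > 0L)
    message(n_unknown, " member id(s) absent from the catalog dropped")

  size <- lengths(clean)
  keep <- size >= min_size
  dropped <- data.frame(set_id = names(members)[!keep], size = size[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(dropped))
    message(nrow(dropped), " set(s) below min_size = ", min_size, " excluded")
  if (!any(keep))
    stop("no gene set meets min_size = ", min_size)

  out <- data.frame(set_id = names(members)[keep],
                    namespace = namespace[keep],
                    size = unname(size[keep]),
                    stringsAsFactors = FALSE)
  out$members <- unname(clean[keep])
  rownames(out) <- NULL
  structure(out, dropped = dropped, n_unknown_members = n_unknown,
            min_size = min_size, class = c("gene_sets", "data.frame"))
}

.norm_namespace <- function(ns) {
  up <- toupper(as.character(ns))
  up[up %in% c("BIOLOGICAL_PROCESS", "GO:BP")] <- "BP"
  up[up %in% c("MOLECULAR_FUNCTION", "GO:MF")] <- "MF"
  up[up %in% c("CELLULAR_COMPONENT", "GO:CC")] <- "CC"
  ifelse(up %in% c("BP", "MF", "CC"), up, "other")
}

#' Read gene sets from a GMT file
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated. The description field is interpreted as the GO namespace
#' when it reads as BP/MF/CC (or the spelled-out forms); anything else maps to
#' `"other"`.
#'
#' @inheritParams gene_sets
#' @param path GMT file path.
#' @return A [gene_sets()] collection.
#' @export
read_gene_sets <- function(path, catalog, min_size = 15L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop("malformed GMT line ", lineno[which(short)[1L]],
         ": expected set id, description and at least one member")
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(members) <- ids
  gene_sets(members, namespace = desc, catalog = catalog, min_size = min_size)
}

#' Write gene sets as GMT
#'
#' The namespace is written into the description field, so a read/write cycle
#' through [read_gene_sets()] is lossless for set id, namespace and the
#' catalog-resolved membership.
#'
#' @param sets a [gene_sets()] collection.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  out <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_id[i], sets$namespace[i], sets$members[[i]]),
          collapse = "\t")
  }, "")
  writeLines(out, path)
  invisible(path)
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("Gene sets:", nrow(x), "set(s) (min size ", attr(x, "min_size"), ")\n", sep = "")
  cat("Namespaces:", paste(sprintf("%s=%d", names(table(x$namespace)),
                                   table(x$namespace)), collapse = ", "), "\n")
  cat("Sizes: ", paste(range(x$size), collapse = "-"), "\n", sep = "")
  dropped <- attr(x, "dropped")
  if (NROW(dropped)) cat(nrow(dropped), "set(s) were dropped by the size filter\n")
  invisible(x)
}
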