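#' Tile the genome with sliding detection windows
#'
#' Each chromosome is tiled with fixed-size windows advanced by `step`:
#' starts 0, step, 2*step, ... while `start + window_size <=` the chromosome
#' length, plus one truncated terminal window ending at the chromosome end
#' when the stepping rule would otherwise leave a tail uncovered. A
#' chromosome shorter than the window yields a single whole-chromosome
#' window. A gene belongs to a window when its start coordinate lies in
#' `[window start, window end)`, so every gene is scanned by at least one
#' window and overlapping windows share genes.
#'
#' @param catalog a [gene_catalog()].
#' @param window_size window width in bp (default 1e6, i.e. 1 Mbp).
#' @param step slide distance in bp (default 2.5e5); must not exceed
#'   `window_size`.
#' @return A `genome_windows` data.frame: `window` (index), `chrom`, `start`,
#'   `end`, `n_genes`, and a `genes` list-column of catalog row indices.
#' @examples
#' cat <- gene_catalog(
#'   data.frame(gene_id = c("A", "B"), chrom = "chr1",
#'              start = c(1e5, 1.5e6), end = c(2e5, 1.6e6)),
#'   chrom_lengths = c(chr1 = 2e6))
#' build_windows(cat)  # 5 windows: starts 0, 0.25, 0.5, 0.75, 1 Mbp
#' @export
build_windows <- function(catalog, window_size = 1e6, step = 2.5e5) {
  stopifnot(window_size > 0, step > 0)
  if (step > window_size)
    stop("`step` must not exceed `window_size`")
  cl <- chrom_lengths(catalog)
  pieces <- lapply(names(cl), function(chrom) {
    L <- cl[[chrom]]
    if (L < window_size) {
      message("chromosome ", chrom, " (", L, " bp) shorter than the window; ",
              "using a single whole-chromosome window")
      starts <- 0
      ends <- L
    } else {
      starts <- seq(0, L - window_size, by = step)
      ends <- starts + window_size
      if (max(ends) < L) {          # terminal truncated window covers the tail
        starts <- c(starts, max(starts) + step)
        ends <- c(ends, L)
      }
    }
    onchr <- which(catalog$chrom == chrom)
    gs <- catalog$start[onchr]
    genes <- lapply(seq_along(starts),
                    function(k) onchr[gs >= starts[k] & gs < ends[k]])
    data.frame(chrom = chrom, start = starts, end = ends,
               n_genes = lengths(genes), genes = I(genes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- cbind(window = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, window_size = window_size, step = step,
            class = c("genome_windows", "data.frame"))
}

#' @export
print.genome_windows <- function(x, ...) {
  cat("Genome windows: ", nrow(x), " window(s), size ",
      attr(x, "window_size"), " bp, step ", attr(x, "step"), " bp\n", sep = "")
  cat("Chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  cat("Genes per window:", paste(range(x$n_genes), collapse = "-"), "\n")
  invisible(x)
}
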