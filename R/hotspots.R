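#' Merge consecutive enriched windows into runs
#'
#' For each gene set and chromosome, maximal groups of enriched windows that
#' are positionally overlapping or adjacent are merged into a single run.
#' The run's gene vector `d` marks the genes carried forward to boundary
#' refinement: with `inclusion = "union"` (default) a gene is included when
#' it lies in at least one of the run's windows; `"strict"` keeps only genes
#' covered by more than one window (the literal reading of the published
#' inclusion rule, which excludes genes seen by a single enriched window).
#'
#' @param cells an [scan_windows()] cell table.
#' @param ctx the [build_indicators()] context the cells came from.
#' @param inclusion `"union"` or `"strict"` (see Details).
#' @return A `merged_runs` data.frame: `set`, `set_id`, `chrom`, `n_windows`,
#'   `start`, `end` (bp of the merged span), `n_genes`, and a `genes`
#'   list-column of catalog row indices.
#' @export
merge_runs <- function(cells, ctx, inclusion = c("union", "strict")) {
  inclusion <- match.arg(inclusion)
  stopifnot(inherits(ctx, "indicator_context"))
  enr <- cells[cells$enriched, , drop = FALSE]
  empty <- data.frame(set = integer(), set_id = character(),
                      chrom = character(), n_windows = integer(),
                      start = numeric(), end = numeric(),
                      n_genes = integer(), genes = I(list()),
                      stringsAsFactors = FALSE)
  if (!nrow(enr))
    return(structure(empty, inclusion = inclusion,
                     class = c("merged_runs", "data.frame")))
  rows <- list()
  n_empty <- 0L
  for (grp in split(enr, list(enr$set, enr$chrom), drop = TRUE)) {
    grp <- grp[order(grp$win_start), , drop = FALSE]
    run_id <- cumsum(c(1L, as.integer(grp$win_start[-1] > cummax(grp$win_end)[-nrow(grp)])))
    for (run in split(grp, run_id)) {
      widx <- run$window
      s <- Matrix::colSums(ctx$B[widx, , drop = FALSE])  # window coverage count per gene
      g <- which(if (inclusion == "union") s >= 1 else s > 1)
      if (!length(g)) { n_empty <- n_empty + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        set = run$set[1L], set_id = run$set_id[1L], chrom = run$chrom[1L],
        n_windows = length(widx),
        start = min(run$win_start), end = max(run$win_end),
        n_genes = length(g), genes = I(list(g)),
        stringsAsFactors = FALSE)
    }
  }
  if (n_empty)
    message(n_empty, " run(s) left no gene under the strict inclusion rule and were dropped")
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$set, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, inclusion = inclusion, class = c("merged_runs", "data.frame"))
}

#' Refine the boundaries of one merged run
#'
#' The run's genes (in catalog order) are trimmed from both ends by the
#' marginal profile optimization: for every position `g` the enrichment p of
#' the suffix subset (genes `g..n` against the full set, genome background
#' `M`, set size `y`) and of the prefix subset (genes `1..g`) is evaluated;
#' the optimal region takes its left boundary from the argmin of the suffix
#' profile and its right boundary from the argmin of the prefix profile, each
#' computed on the full run. Ties are broken toward the smaller region. When
#' the two argmins cross (left boundary beyond the right), the run is
#' degenerate and is reported unrefined rather than silently fixed.
#'
#' @param run one row of a [merge_runs()] table (or a list with `genes`
#'   — catalog indices — and `set` — set column index).
#' @param ctx the [build_indicators()] context.
#' @return A one-row data.frame describing the refined hotspot: `set`,
#'   `set_id`, `namespace`, `chrom`, `start`, `end` (bp), `gene_from`,
#'   `gene_to` (catalog indices), `n_genes`, `genes` (list of gene ids), `z`,
#'   `y`, `p`, `degenerate`.
#' @export
refine_boundaries <- function(run, ctx) {
  stopifnot(inherits(ctx, "indicator_context"))
  g <- sort(unlist(run$genes))
  l <- run$set[[1L]]
  if (!length(g)) stop("run gene span is empty")
  memb <- as.integer(ctx$P[g, l] > 0)
  if (sum(memb) < 1L) stop("run contains no member of the gene set")
  n <- length(g)
  y <- Matrix::colSums(ctx$P)[l]
  # suffix profile: subsets genes[a..n]; prefix profile: subsets genes[1..b]
  suf_z <- rev(cumsum(rev(memb)))
  suf_p <- hypergeom_upper_tail(ctx$M, n:1, y, suf_z)
  pre_z <- cumsum(memb)
  pre_p <- hypergeom_upper_tail(ctx$M, 1:n, y, pre_z)
  a <- max(which(suf_p == min(suf_p)))  # deepest left trim among ties
  b <- min(which(pre_p == min(pre_p)))  # deepest right trim among ties
  degenerate <- a > b
  if (degenerate) { a <- 1L; b <- n }   # report the unrefined span, flagged
  o <- g[a:b]
  z <- sum(memb[a:b])
  p <- hypergeom_upper_tail(ctx$M, b - a + 1L, y, z)
  data.frame(set = l, set_id = ctx$sets$set_id[l],
             namespace = ctx$sets$namespace[l],
             chrom = ctx$catalog$chrom[o[1L]],
             start = ctx$catalog$start[o[1L]],
             end = max(ctx$catalog$end[o]),
             gene_from = o[1L], gene_to = o[length(o)],
             n_genes = length(o),
             genes = I(list(ctx$catalog$gene_id[o])),
             z = z, y = unname(y), p = p,
             degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Refine all runs and emit significant hotspots
#'
#' Applies [refine_boundaries()] to every merged run and keeps refined
#' regions whose Bonferroni-adjusted p (using the scan's declared test count)
#' is below `alpha`. Degenerate runs are reported and never emitted.
#'
#' @param runs a [merge_runs()] table.
#' @param ctx the [build_indicators()] context.
#' @param alpha significance level (default 0.05).
#' @param n_tests the Bonferroni factor, normally `attr(cells, "n_tests")`
#'   from the scan stage.
#' @return An `sfh_hotspots` data.frame with the refined-region columns plus
#'   `p_adj`; attribute `degenerate` holds unrefined runs.
#' @export
call_hotspots <- function(runs, ctx, alpha = 0.05, n_tests) {
  stopifnot(is.numeric(n_tests), n_tests >= 1)
  refined <- lapply(seq_len(NROW(runs)),
                    function(i) refine_boundaries(runs[i, , drop = FALSE], ctx))
  refined <- if (length(refined)) do.call(rbind, refined) else NULL
  if (is.null(refined)) {
    out <- data.frame(set = integer(), set_id = character(),
                      namespace = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      gene_from = integer(), gene_to = integer(),
                      n_genes = integer(), genes = I(list()),
                      z = numeric(), y = numeric(), p = numeric(),
                      degenerate = logical(), p_adj = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(out, degenerate = out[0L, ],
                     class = c("sfh_hotspots", "data.frame")))
  }
  refined$p_adj <- pmin(1, refined$p * n_tests)
  degen <- refined[refined$degenerate, , drop = FALSE]
  if (nrow(degen))
    message(nrow(degen), " run(s) degenerate after boundary refinement; reported unrefined")
  out <- refined[!refined$degenerate & refined$p_adj < alpha, , drop = FALSE]
  out <- out[order(out$p_adj, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, degenerate = degen, class = c("sfh_hotspots", "data.frame"))
}
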