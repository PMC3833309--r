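#' Detect spatial functional hotspots
#'
#' The main fitting function. Slides a fixed-size window along every
#' chromosome of `catalog`, tests each window against each gene set with the
#' upper-tail hypergeometric (Fisher exact) test, Bonferroni-adjusts over the
#' tests actually performed, merges consecutive enriched windows per set into
#' runs, refines each run's boundaries by marginal prefix/suffix trimming,
#' and emits refined regions that remain significant as spatial functional
#' hotspots (SFHs).
#'
#' @param catalog a [gene_catalog()].
#' @param sets a [gene_sets()] collection resolved against `catalog`.
#' @param window_size detection window in bp (default 1 Mbp).
#' @param step slide distance in bp (default 0.25 Mbp).
#' @param alpha Bonferroni family-wise level for both the window scan and the
#'   refined-region call (default 0.05).
#' @param inclusion merged-run gene inclusion rule, `"union"` (default) or
#'   `"strict"`; see [merge_runs()].
#' @return An object of class `"sfh"`: a list with elements `hotspots`
#'   ([call_hotspots()] table), `runs`, `cells`, `windows`, `catalog`,
#'   `sets`, `n_tests`, `params`, `call`. Use [summary()], [plot()],
#'   [as.data.frame()] and [write_hotspots()] on it.
#' @examples
#' sim <- simulate_genome(seed = 1)
#' fit <- sfh_detect(sim$catalog, sim$sets)
#' fit
#' summary(fit)
#' @export
sfh_detect <- function(catalog, sets, window_size = 1e6, step = 2.5e5,
                       alpha = 0.05, inclusion = c("union", "strict")) {
  inclusion <- match.arg(inclusion)
  windows <- build_windows(catalog, window_size = window_size, step = step)
  ctx <- build_indicators(catalog, windows, sets)
  cells <- scan_windows(ctx, alpha = alpha)
  runs <- merge_runs(cells, ctx, inclusion = inclusion)
  hotspots <- call_hotspots(runs, ctx, alpha = alpha,
                            n_tests = max(1L, attr(cells, "n_tests")))
  structure(list(hotspots = hotspots, runs = runs, cells = cells,
                 windows = windows, catalog = catalog, sets = sets,
                 n_tests = attr(cells, "n_tests"),
                 params = list(window_size = window_size, step = step,
                               alpha = alpha, inclusion = inclusion),
                 call = match.call()),
            class = "sfh")
}

#' @export
print.sfh <- function(x, ...) {
  cat("Spatial functional hotspot scan\n")
  cat("  genes:", nrow(x$catalog), " sets:", nrow(x$sets),
      " windows:", nrow(x$windows), "\n")
  cat("  tests performed (Bonferroni factor):", x$n_tests, "\n")
  cat("  enriched windows:", sum(x$cells$enriched),
      " merged runs:", nrow(x$runs), "\n")
  cat("  hotspots at alpha ", x$params$alpha, ": ", nrow(x$hotspots),
      "\n", sep = "")
  if (nrow(x$hotspots)) {
    top <- utils::head(as.data.frame(x$hotspots)[
      c("set_id", "namespace", "chrom", "start", "end", "n_genes", "z", "p_adj")], 5L)
    print(top)
  }
  invisible(x)
}

#' Summarize a hotspot scan
#'
#' Per-chromosome hotspot counts and densities (hotspots per Mbp of declared
#' chromosome length), hotspot length and gene-count distributions, and
#' namespace breakdown — the standard descriptive view of a genome-wide SFH
#' catalog.
#'
#' @param object an [sfh_detect()] fit.
#' @param ... unused.
#' @return A list of class `summary.sfh`.
#' @export
summary.sfh <- function(object, ...) {
  h <- object$hotspots
  cl <- chrom_lengths(object$catalog)
  counts <- table(factor(h$chrom, levels = names(cl)))
  per_chrom <- data.frame(chrom = names(cl),
                          length_mbp = unname(cl) / 1e6,
                          n_hotspots = as.integer(counts),
                          density_per_mbp = as.integer(counts) / (unname(cl) / 1e6),
                          stringsAsFactors = FALSE)
  structure(list(n_hotspots = nrow(h),
                 n_sets_enriched = length(unique(h$set_id)),
                 by_namespace = table(h$namespace),
                 per_chrom = per_chrom,
                 mean_length_mbp = if (nrow(h)) mean((h$end - h$start) / 1e6) else NA_real_,
                 mean_n_genes = if (nrow(h)) mean(h$n_genes) else NA_real_,
                 n_tests = object$n_tests,
                 alpha = object$params$alpha),
            class = "summary.sfh")
}

#' @export
print.summary.sfh <- function(x, ...) {
  cat("SFH summary:", x$n_hotspots, "hotspot(s) over",
      x$n_sets_enriched, "gene set(s)\n")
  if (length(x$by_namespace))
    cat("  by namespace:", paste(sprintf("%s=%d", names(x$by_namespace),
                                         x$by_namespace), collapse = ", "), "\n")
  cat("  mean length:", round(x$mean_length_mbp, 3), "Mbp;  mean genes:",
      round(x$mean_n_genes, 2), "\n")
  cat("  per chromosome:\n")
  print(x$per_chrom, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.sfh <- function(x, ...) {
  h <- as.data.frame(x$hotspots)
  h$genes <- vapply(h$genes, paste, "", collapse = ",")
  h
}

#' Plot the enrichment landscape of a scan
#'
#' Draws the strongest Bonferroni-adjusted p value per window (as -log10)
#' along the concatenated genome, with chromosome boundaries dashed and
#' emitted hotspots marked at the top.
#'
#' @param x an [sfh_detect()] fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sfh <- function(x, ...) {
  cl <- chrom_lengths(x$catalog)
  offs <- stats::setNames(cumsum(c(0, unname(cl)))[seq_along(cl)], names(cl))
  best <- tapply(x$cells$p_adj, x$cells$window, min)
  w <- x$windows[as.integer(names(best)), , drop = FALSE]
  pos <- (offs[w$chrom] + (w$start + w$end) / 2) / 1e6
  graphics::plot(pos, -log10(pmax(best, .Machine$double.xmin)),
                 pch = 16, cex = 0.4, col = "grey40",
                 xlab = "genome position (Mbp)",
                 ylab = expression(-log[10] ~ "adjusted p (best set per window)"),
                 ...)
  graphics::abline(v = cumsum(unname(cl)) / 1e6, lty = 2, col = "grey70")
  graphics::abline(h = -log10(x$params$alpha), col = "red3", lty = 3)
  h <- x$hotspots
  if (nrow(h))
    graphics::points((offs[h$chrom] + (h$start + h$end) / 2) / 1e6,
                     rep(graphics::par("usr")[4] * 0.97, nrow(h)),
                     pch = 25, bg = "red3", col = "red3", cex = 0.7)
  invisible(x)
}

#' Export hotspot tables
#'
#' `write_hotspots()` writes the tab-delimited hotspot table (set id,
#' namespace, chromosome, start, end, gene count, gene list, overlap z, set
#' size y, p, adjusted p); `write_hotspots_bed()` writes the hotspot
#' intervals as BED4 (name = set id).
#'
#' @param sfh an [sfh_detect()] fit (or its `hotspots` table).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hotspots <- function(sfh, path) {
  h <- if (inherits(sfh, "sfh")) as.data.frame(sfh) else {
    h2 <- as.data.frame(sfh); h2$genes <- vapply(h2$genes, paste, "", collapse = ","); h2
  }
  cols <- c("set_id", "namespace", "chrom", "start", "end", "n_genes",
            "genes", "z", "y", "p", "p_adj")
  utils::write.table(h[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hotspots
#' @export
write_hotspots_bed <- function(sfh, path) {
  h <- if (inherits(sfh, "sfh")) sfh$hotspots else sfh
  writeLines(sprintf("%s\t%s\t%s\t%s", h$chrom,
                     format(h$start, scientific = FALSE, trim = TRUE),
                     format(h$end, scientific = FALSE, trim = TRUE),
                     h$set_id), path)
  invisible(path)
}
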