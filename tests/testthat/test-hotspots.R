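# Build a context in which chosen windows are enriched for one set and run
# the merge stage; gene coordinates come from toy_catalog (100 kb spacing).
merge_fixture <- function(n_genes, window_genes, set_members, alpha = 0.05) {
  cat <- toy_catalog(n_genes, chrom_len = n_genes * 1e5 + 1e5)
  ctx <- toy_context(cat, window_genes, set_members)
  # give windows real coordinates: each window spans its genes' starts
  ctx$windows$start <- vapply(window_genes, function(g) min(cat$start[g]), 0)
  ctx$windows$end <- vapply(window_genes, function(g) max(cat$start[g]) + 1e5, 0)
  cells <- scan_windows(ctx, alpha = alpha)
  list(ctx = ctx, cells = cells)
}

test_that("overlapping enriched windows for one set merge into one run with the gene union", {
  fx <- merge_fixture(20, window_genes = list(1:10, 6:15, 16:20),
                      set_members = list(s = sprintf("g%02d", 2:12)))
  # force both left windows enriched regardless of p by raising alpha via cells
  fx$cells$enriched <- fx$cells$window %in% c(1L, 2L)
  runs <- merge_runs(fx$cells, fx$ctx)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$genes[[1L]], 1:15)         # union of the two windows
  expect_equal(runs$n_windows, 2L)
})

test_that("enriched windows on different chromosomes or separated loci form separate runs", {
  sim <- simulate_genome(n_genes = 600, n_chromosomes = 2,
                         chromosome_length = 1e7, n_sets = 10,
                         set_size_range = c(16, 25),
                         islands = list(
                           island_spec(set = 1, chrom = "chr1", start = 2e6,
                                       set_size = 24, n_members = 12),
                           island_spec(set = 1, chrom = "chr2", start = 6e6,
                                       set_size = 24, n_members = 12)),
                         seed = 3)
  fit <- suppressMessages(sfh_detect(sim$catalog, sim$sets))
  runs <- fit$runs[fit$runs$set_id == "S01", ]
  expect_equal(sort(unique(runs$chrom)), c("chr1", "chr2"))
  expect_gte(nrow(runs), 2L)
})

test_that("a single enriched window yields a run of that window's genes", {
  fx <- merge_fixture(12, window_genes = list(1:6, 7:12),
                      set_members = list(s = sprintf("g%02d", 1:5)))
  fx$cells$enriched <- fx$cells$window == 1L
  runs <- merge_runs(fx$cells, fx$ctx)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$n_windows, 1L)
  expect_equal(runs$genes[[1L]], 1:6)
})

test_that("the strict inclusion variant keeps only genes seen by more than one window", {
  fx <- merge_fixture(20, window_genes = list(1:10, 6:15, 16:20),
                      set_members = list(s = sprintf("g%02d", 2:12)))
  fx$cells$enriched <- fx$cells$window %in% c(1L, 2L)
  runs <- merge_runs(fx$cells, fx$ctx, inclusion = "strict")
  expect_equal(runs$genes[[1L]], 6:10)          # the windows' intersection
})

test_that("flanking non-members are trimmed and membership patterns refine to the derived optimum", {
  cat <- toy_catalog(30, chrom_len = 4e6)
  memb_pattern <- c(0, 1, 1, 1, 0)
  ctx <- toy_context(cat, window_genes = list(1:5, 6:30),
                     set_members = list(s = cat$gene_id[c(2:4, 10, 20)]))
  run <- list(genes = list(1:5), set = 1L)
  hs <- refine_boundaries(run, ctx)
  opt <- oracle_refine(memb_pattern, M = 30, y = 5)
  expect_equal(hs$gene_from, opt$a)
  expect_equal(hs$gene_to, opt$b)
  expect_equal(hs$gene_from, 2L)               # flanking non-members trimmed
  expect_equal(hs$gene_to, 4L)
  expect_equal(hs$p, opt$p, tolerance = 1e-12)
})

test_that("an all-member run refines to the entire span and a single member to itself", {
  cat <- toy_catalog(30, chrom_len = 4e6)
  ctx <- toy_context(cat, window_genes = list(1:6, 7:30),
                     set_members = list(all6 = cat$gene_id[1:6],
                                        one = cat$gene_id[c(3, 15, 25)]))
  all_run <- refine_boundaries(list(genes = list(1:6), set = 1L), ctx)
  expect_equal(c(all_run$gene_from, all_run$gene_to), c(1L, 6L))
  single <- refine_boundaries(list(genes = list(1:6), set = 2L), ctx)
  expect_equal(c(single$gene_from, single$gene_to), c(3L, 3L))
  expect_equal(single$n_genes, 1L)
})

test_that("refinement agrees exactly with exhaustive trim evaluation on random runs", {
  set.seed(21)
  cat <- toy_catalog(40, chrom_len = 5e6)
  for (i in 1:60) {
    n <- sample(3:25, 1)
    memb <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(memb) == 0) memb[sample(n, 1)] <- 1L
    extra <- sample(setdiff(seq(n + 1, 40), integer()), max(0, 15 - sum(memb)))
    members <- c(cat$gene_id[seq_len(n)][memb == 1], cat$gene_id[extra])
    ctx <- toy_context(cat, window_genes = list(seq_len(n), seq(n + 1, 40)),
                       set_members = list(s = members))
    opt <- oracle_refine(memb, M = 40, y = length(members))
    if (is.null(opt)) {
      hs <- refine_boundaries(list(genes = list(seq_len(n)), set = 1L), ctx)
      expect_true(hs$degenerate)
    } else {
      hs <- refine_boundaries(list(genes = list(seq_len(n)), set = 1L), ctx)
      expect_false(hs$degenerate)
      expect_equal(c(hs$gene_from, hs$gene_to), c(opt$a, opt$b))
      expect_equal(hs$p, opt$p, tolerance = 1e-12)
      # endpoint genes are set members
      expect_equal(memb[opt$a], 1L)
      expect_equal(memb[opt$b], 1L)
    }
  }
})

test_that("refinement never increases the enrichment p, nor does re-refinement", {
  set.seed(22)
  cat <- toy_catalog(40, chrom_len = 5e6)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    memb <- rbinom(n, 1, 0.5)
    if (sum(memb) == 0) memb[sample(n, 1)] <- 1L
    ctx <- toy_context(cat, window_genes = list(seq_len(n), seq(n + 1, 40)),
                       set_members = list(s = cat$gene_id[seq_len(n)][memb == 1]))
    hs <- refine_boundaries(list(genes = list(seq_len(n)), set = 1L), ctx)
    if (hs$degenerate) next
    p_full <- hypergeom_upper_tail(40, n, sum(memb), sum(memb))
    expect_lte(hs$p, p_full)
    # the procedure is one-pass by design; re-applying it to the refined
    # span can only tighten further, never worsen, and keeps member endpoints
    hs2 <- refine_boundaries(list(genes = list(hs$gene_from:hs$gene_to), set = 1L), ctx)
    expect_lte(hs2$p, hs$p)
    expect_gte(hs2$gene_from, hs$gene_from)
    expect_lte(hs2$gene_to, hs$gene_to)
  }
})

test_that("hotspot emission follows the adjusted-p threshold and summaries are arithmetic", {
  sim <- simulate_genome(seed = 5)
  fit <- suppressMessages(sfh_detect(sim$catalog, sim$sets))
  expect_true(all(fit$hotspots$p_adj < 0.05))
  expect_true(all(!fit$hotspots$degenerate))
  s <- summary(fit)
  expect_equal(s$n_hotspots, nrow(fit$hotspots))
  expect_equal(s$mean_length_mbp,
               mean((fit$hotspots$end - fit$hotspots$start) / 1e6))
  expect_equal(sum(s$per_chrom$n_hotspots), nrow(fit$hotspots))
  # suppressed below threshold: rerun the call with an alpha under the best p
  tight <- call_hotspots(fit$runs,
                         build_indicators(fit$catalog, fit$windows, fit$sets),
                         alpha = min(fit$hotspots$p_adj) / 10,
                         n_tests = fit$n_tests)
  expect_equal(nrow(tight), 0L)
})

test_that("hotspot tables export as TSV and BED", {
  sim <- simulate_genome(seed = 5)
  fit <- suppressMessages(sfh_detect(sim$catalog, sim$sets))
  tsv <- tempfile(); bed <- tempfile()
  write_hotspots(fit, tsv)
  write_hotspots_bed(fit, bed)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(fit$hotspots))
  expect_equal(back$start, fit$hotspots$start)
  bed_back <- read.delim(bed, header = FALSE)
  expect_equal(bed_back[[2]], fit$hotspots$start)
  expect_equal(bed_back[[4]], fit$hotspots$set_id)
})
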