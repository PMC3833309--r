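test_that("BED records map directly onto catalog fields and are deduplicated and sorted", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t500\tGENE_A",
               "chr1\t900\t1200\tGENE_B",
               "chr1\t100\t500\tGENE_A",       # exact duplicate collapses
               "chr1\t20\t80\tGENE_C"),        # out of order
             bed)
  cat <- suppressMessages(read_gene_annotation(bed, "bed"))
  expect_equal(nrow(cat), 3L)
  expect_equal(cat$gene_id, c("GENE_C", "GENE_A", "GENE_B"))  # sorted by start
  expect_equal(cat$start[cat$gene_id == "GENE_A"], 100)
  expect_equal(cat$end[cat$gene_id == "GENE_A"], 500)
})

test_that("malformed BED lines and conflicting duplicates are rejected with diagnostics", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t500\tA", "chr1\t600\t700"), bed)
  expect_error(read_gene_annotation(bed, "bed"), "line 2")
  writeLines(c("chr1\t100\t500\tA", "chr1\t600\t700\tA"), bed)
  expect_error(suppressMessages(read_gene_annotation(bed, "bed")),
               "duplicate gene_id")
  writeLines(c("chr1\t100\tfoo\tA"), bed)
  expect_error(read_gene_annotation(bed, "bed"), "non-numeric")
})

test_that("GTF genes are converted from 1-based inclusive and sorted", {
  skip_if_not_installed("rtracklayer")
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t901\t1200\t.\t+\t.\tgene_id "B";',
    'chr2\tsrc\tgene\t51\t200\t.\t-\t.\tgene_id "C";',
    'chr1\tsrc\tgene\t101\t500\t.\t+\t.\tgene_id "A";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "A";'), gtf)
  cat <- suppressMessages(read_gene_annotation(gtf, "gtf"))
  expect_equal(cat$gene_id, c("A", "B", "C"))
  expect_equal(cat$start, c(100, 900, 50))   # 1-based 101 -> 0-based 100
  expect_equal(cat$end, c(500, 1200, 200))
})

test_that("genes on undeclared chromosomes are rejected and reported", {
  genes <- data.frame(gene_id = c("A", "B"), chrom = c("chr1", "chrUn"),
                      start = c(0, 0), end = c(100, 100))
  expect_message(cat <- gene_catalog(genes, c(chr1 = 1000)), "rejected")
  expect_equal(nrow(cat), 1L)
  expect_equal(attr(cat, "rejected")$gene_id, "B")
})

test_that("GMT size filter sits exactly at the declared boundary", {
  cat <- toy_catalog(20)
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c(
    paste(c("S14", "BP", sprintf("g%02d", 1:14)), collapse = "\t"),
    paste(c("S15", "MF", sprintf("g%02d", 1:15)), collapse = "\t")), gmt)
  sets <- suppressMessages(read_gene_sets(gmt, cat, min_size = 15))
  expect_equal(sets$set_id, "S15")               # 15 retained, 14 excluded
  expect_equal(attr(sets, "dropped")$set_id, "S14")
  expect_equal(sets$namespace, "MF")
})

test_that("unknown GMT members are dropped via catalog intersection, with a report", {
  cat <- toy_catalog(20)
  gmt <- tempfile(fileext = ".gmt")
  writeLines(paste(c("S1", "CC", sprintf("g%02d", 1:15), "NOT_A_GENE"),
                   collapse = "\t"), gmt)
  expect_message(sets <- read_gene_sets(gmt, cat, min_size = 15), "absent")
  expect_equal(sets$size, 15L)
  expect_false("NOT_A_GENE" %in% sets$members[[1L]])
})

test_that("GMT parse errors name the offending line; empty files are rejected", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tBP\tg01", "S2\tdescription_only"), gmt)
  expect_error(read_gene_sets(gmt, toy_catalog(), min_size = 1), "line 2")
  writeLines(character(), gmt)
  expect_error(read_gene_sets(gmt, toy_catalog(), min_size = 1), "empty")
})

test_that("window tiling follows the stepping convention", {
  cat <- toy_catalog(n = 10, chrom_len = 2e6)
  w <- build_windows(cat, window_size = 1e6, step = 2.5e5)
  expect_equal(nrow(w), 5L)
  expect_equal(w$start, c(0, 2.5e5, 5e5, 7.5e5, 1e6))
  expect_equal(w$end - w$start, rep(1e6, 5))
  # adjacent default windows share 0.75 Mbp
  expect_equal(w$end[1] - w$start[2], 7.5e5)
})

test_that("a truncated terminal window covers the chromosome tail", {
  cat <- suppressMessages(gene_catalog(
    data.frame(gene_id = c("a", "b"), chrom = "chr1",
               start = c(0, 2.05e6), end = c(1e4, 2.06e6)),
    chrom_lengths = c(chr1 = 2.1e6)))
  w <- build_windows(cat, 1e6, 2.5e5)
  expect_equal(max(w$end), 2.1e6)                  # tail covered
  expect_lt(w$end[nrow(w)] - w$start[nrow(w)], 1e6)  # truncated
  expect_true(all(lengths(w$genes) == w$n_genes))
  expect_true(2L %in% unlist(w$genes))             # tail gene scannable
})

test_that("a chromosome shorter than the window becomes a single window", {
  cat <- suppressMessages(gene_catalog(
    data.frame(gene_id = "a", chrom = "chr1", start = 100, end = 200),
    chrom_lengths = c(chr1 = 5e5)))
  expect_message(w <- build_windows(cat, 1e6, 2.5e5), "shorter")
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$start, w$end), c(0, 5e5))
})

test_that("window coverage and gene-membership invariants hold on random catalogs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 50
    genes <- data.frame(gene_id = sprintf("g%03d", 1:n),
                        chrom = sample(c("chrA", "chrB"), n, TRUE),
                        start = round(runif(n, 0, 4.9e6)))
    genes$end <- genes$start + 1e4
    cat <- suppressMessages(gene_catalog(genes, c(chrA = 5e6, chrB = 5e6)))
    w <- build_windows(cat, 1e6, 2.5e5)
    # every base covered by >= 1 window
    for (chrom in c("chrA", "chrB")) {
      wc <- w[w$chrom == chrom, ]
      probes <- seq(0, 5e6 - 1, length.out = 200)
      covered <- vapply(probes, function(b) any(wc$start <= b & b < wc$end), TRUE)
      expect_true(all(covered))
    }
    # each gene counted in >= 1 window when step < window size
    counts <- tabulate(unlist(w$genes), nbins = n)
    expect_true(all(counts >= 1))
    expect_gte(sum(w$n_genes), n)
    # membership rule: gene start inside [window start, window end)
    for (k in sample(nrow(w), 10)) {
      g <- w$genes[[k]]
      if (length(g))
        expect_true(all(cat$start[g] >= w$start[k] & cat$start[g] < w$end[k]))
    }
  }
})

test_that("BED and GMT write/read cycles are lossless for the carried fields", {
  sim <- simulate_genome(n_genes = 200, n_chromosomes = 2,
                         chromosome_length = 5e6, n_sets = 8,
                         set_size_range = c(16, 30), islands = list(),
                         seed = 7)
  bed <- tempfile(fileext = ".bed"); lenf <- tempfile(); gmt <- tempfile()
  write_bed(sim$catalog, bed)
  write_chromosome_lengths(chrom_lengths(sim$catalog), lenf)
  write_gmt(sim$sets, gmt)
  cat2 <- read_gene_annotation(bed, "bed", read_chromosome_lengths(lenf))
  expect_equal(as.data.frame(cat2), as.data.frame(sim$catalog))
  expect_equal(chrom_lengths(cat2), chrom_lengths(sim$catalog))
  sets2 <- suppressMessages(read_gene_sets(gmt, cat2, min_size = 15))
  expect_equal(sets2$set_id, sim$sets$set_id)
  expect_equal(sets2$namespace, sim$sets$namespace)
  expect_equal(lapply(sets2$members, sort), lapply(sim$sets$members, sort))
})
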