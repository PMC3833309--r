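# Independent oracles used across the suite. None of these share code with
# the package implementation.

# Exact upper-tail hypergeometric probability by direct combinatorial
# summation with exact-integer binomial coefficients (all counts fit a
# double exactly for M <= 40).
oracle_tail <- function(M, x, y, z) {
  hs <- z:min(x, y)
  if (z > min(x, y)) return(0)
  sum(choose(y, hs) * choose(M - y, x - hs)) / choose(M, x)
}

# Brute-force subset enumeration: over all C(M, x) window draws, the
# fraction with overlap >= z against a fixed set of y genes. Tiny M only.
oracle_tail_enum <- function(M, x, y, z) {
  set_genes <- seq_len(y)
  draws <- utils::combn(M, x)
  mean(apply(draws, 2L, function(d) sum(d %in% set_genes) >= z))
}

# Exhaustive prefix/suffix trim evaluation for boundary refinement.
# memb: 0/1 membership of the run's genes in catalog order; background M,
# set size y. Returns the optimal (a, b) under the marginal rule with ties
# broken toward the smaller region, or NULL when the argmins cross.
oracle_refine <- function(memb, M, y) {
  n <- length(memb)
  p_suffix <- numeric(n)
  p_prefix <- numeric(n)
  for (g in seq_len(n)) {
    p_suffix[g] <- oracle_tail(M, n - g + 1L, y, sum(memb[g:n]))
    p_prefix[g] <- oracle_tail(M, g, y, sum(memb[1:g]))
  }
  a <- max(which(p_suffix == min(p_suffix)))
  b <- min(which(p_prefix == min(p_prefix)))
  if (a > b) return(NULL)
  list(a = a, b = b, p = oracle_tail(M, b - a + 1L, y, sum(memb[a:b])))
}

# Direct-summation log-rank oracle over pooled risk sets, written
# independently of the package routine (vectorised over the risk-set table
# rather than looped).
oracle_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1L]
  tt <- sort(unique(time[event == 1]))
  n <- sapply(tt, function(t) sum(time >= t))
  n1 <- sapply(tt, function(t) sum(time >= t & g1))
  d <- sapply(tt, function(t) sum(event == 1 & time == t))
  d1 <- sapply(tt, function(t) sum(event == 1 & time == t & g1))
  O <- sum(d1)
  E <- sum(d * n1 / n)
  keep <- n > 1
  V <- sum((d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1))[keep])
  chi <- (O - E)^2 / V
  list(chi_square = chi, p_value = pchisq(chi, 1, lower.tail = FALSE))
}

# Small deterministic catalog used by several unit tests: 10 genes spaced
# 100 kb apart on one 2-Mbp chromosome.
toy_catalog <- function(n = 10, spacing = 1e5, chrom_len = 2e6) {
  suppressMessages(gene_catalog(
    data.frame(gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr1",
               start = (seq_len(n) - 1) * spacing,
               end = (seq_len(n) - 1) * spacing + 5e4),
    chrom_lengths = c(chr1 = chrom_len)))
}

# A context built directly from explicit window/set membership, bypassing
# file IO, for refinement tests.
toy_context <- function(catalog, window_genes, set_members,
                        namespace = "BP") {
  windows <- structure(
    data.frame(window = seq_along(window_genes), chrom = "chr1",
               start = 0, end = attr(catalog, "chrom_lengths")[[1L]],
               n_genes = lengths(window_genes),
               genes = I(window_genes), stringsAsFactors = FALSE),
    window_size = 1e6, step = 1e6, class = c("genome_windows", "data.frame"))
  sets <- suppressMessages(gene_sets(set_members, namespace, catalog,
                                     min_size = 1L))
  build_indicators(catalog, windows, sets)
}
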