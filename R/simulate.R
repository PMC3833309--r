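#' Simulate a gene catalog with planted functional islands
#'
#' Generates a fully synthetic genome for end-to-end testing: background
#' genes placed uniformly at random over a set of equal-length chromosomes
#' and assigned to random gene sets, plus any number of planted "islands" —
#' contiguous loci where most members of one functional set sit side by
#' side, interleaved with a few non-members so boundary refinement has real
#' trimming work to do. This emulates the gene-island architecture the
#' hotspot scan is designed to detect. Identical seeds give byte-identical
#' output files.
#'
#' @param n_genes total genes (default 2000).
#' @param n_chromosomes number of chromosomes (default 5).
#' @param chromosome_length length of every chromosome in bp (default 20 Mbp,
#'   giving a realistic ~20 genes/Mbp at the defaults).
#' @param n_sets number of gene sets (default 50).
#' @param set_size_range size range for non-planted sets (default 20–60).
#' @param islands list of island specifications from [island_spec()];
#'   default: one island of 12 members among 15 contiguous genes. Use
#'   `list()` for a null genome with no positional clustering.
#' @param island_spacing spacing of consecutive island genes in bp
#'   (default 20 kb, so a 15-gene island spans ~0.3 Mbp, well inside one
#'   1-Mbp window).
#' @param gene_length_range background gene length range in bp.
#' @param min_size set-size floor passed to [gene_sets()].
#' @param seed integer seed, or `NULL` to leave the RNG state alone.
#' @return list with `catalog` ([gene_catalog()]), `sets` ([gene_sets()]),
#'   and `truth` — one row per planted island: `set_id`, `chrom`,
#'   `island_start`, `island_end`, `first_member`, `last_member`,
#'   `member_start`, `member_end`, and a `members` list-column.
#' @examples
#' sim <- simulate_genome(seed = 42)
#' sim$truth[, c("set_id", "chrom", "first_member", "last_member")]
#' @export
simulate_genome <- function(n_genes = 2000, n_chromosomes = 5,
                            chromosome_length = 2e7, n_sets = 50,
                            set_size_range = c(20, 60),
                            islands = list(island_spec()),
                            island_spacing = 2e4,
                            gene_length_range = c(1e3, 1e4),
                            min_size = 15L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chromosomes))
  cl <- stats::setNames(rep(chromosome_length, n_chromosomes), chroms)

  genes <- list(); memb_truth <- list()
  gid <- 0L
  next_id <- function(k) sprintf("G%04d", gid + seq_len(k))
  for (isl in islands) {
    k <- isl$n_genes
    if (!isl$chrom %in% chroms) stop("island chromosome not in the genome")
    span <- (k - 1) * island_spacing + island_spacing / 2
    if (isl$start + span > chromosome_length)
      stop("island exceeds chromosome capacity")
    ids <- next_id(k); gid <- gid + k
    starts <- isl$start + (seq_len(k) - 1) * island_spacing
    m <- k - isl$n_members
    nonmember_pos <- if (m > 0) unique(round(seq(1, k, length.out = max(m, 2L))))[seq_len(m)] else integer()
    if (m > 0 && length(nonmember_pos) < m)   # tiny islands: fill from the left
      nonmember_pos <- seq_len(m)
    member_pos <- setdiff(seq_len(k), nonmember_pos)
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = ids, chrom = isl$chrom, start = starts,
      end = starts + island_spacing / 2, stringsAsFactors = FALSE)
    memb_truth[[length(memb_truth) + 1L]] <-
      list(spec = isl, ids = ids, member_pos = member_pos,
           starts = starts, ends = starts + island_spacing / 2)
  }
  n_bg <- n_genes - gid
  if (n_bg < 0L) stop("island genes exceed n_genes")
  if (n_bg > 0L) {
    ids <- next_id(n_bg); gid <- gid + n_bg
    chrom <- sample(chroms, n_bg, replace = TRUE)
    len <- round(stats::runif(n_bg, gene_length_range[1L], gene_length_range[2L]))
    start <- floor(stats::runif(n_bg, 0, chromosome_length - len))
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = ids, chrom = chrom, start = start, end = start + len,
      stringsAsFactors = FALSE)
    bg_ids <- ids
  } else bg_ids <- character()
  catalog <- suppressMessages(gene_catalog(do.call(rbind, genes), cl))

  set_ids <- sprintf("S%02d", seq_len(n_sets))
  namespace <- sample(c("BP", "MF", "CC"), n_sets, replace = TRUE)
  members <- vector("list", n_sets)
  planted <- vapply(islands, `[[`, 0, "set")
  if (any(planted > n_sets)) stop("island set index exceeds n_sets")
  for (l in seq_len(n_sets)) {
    if (l %in% planted) next
    size <- sample(seq(set_size_range[1L], set_size_range[2L]), 1L)
    members[[l]] <- sample(catalog$gene_id, size)
  }
  truth_rows <- list()
  for (tr in memb_truth) {
    isl <- tr$spec
    member_ids <- tr$ids[tr$member_pos]
    already <- length(members[[isl$set]])
    extra <- max(0L, isl$set_size - length(member_ids) - already)
    scatter <- if (extra > 0L) sample(bg_ids, extra) else character()
    members[[isl$set]] <- c(members[[isl$set]], member_ids, scatter)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      set_id = set_ids[isl$set], chrom = isl$chrom,
      island_start = min(tr$starts), island_end = max(tr$ends),
      first_member = member_ids[1L],
      last_member = member_ids[length(member_ids)],
      member_start = tr$starts[tr$member_pos[1L]],
      member_end = tr$ends[tr$member_pos[length(tr$member_pos)]],
      members = I(list(member_ids)), stringsAsFactors = FALSE)
  }
  names(members) <- set_ids
  sets <- suppressMessages(gene_sets(members, namespace, catalog, min_size = min_size))
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(set_id = character(), chrom = character(),
               island_start = numeric(), island_end = numeric(),
               first_member = character(), last_member = character(),
               member_start = numeric(), member_end = numeric(),
               members = I(list()), stringsAsFactors = FALSE)
  list(catalog = catalog, sets = sets, truth = truth)
}

#' Specify a planted functional island
#'
#' @param set index of the gene set receiving the island (default 1).
#' @param n_members island genes belonging to the set (default 12).
#' @param n_genes total contiguous island genes, members plus interleaved
#'   non-members (default 15).
#' @param chrom,start island locus (default chr1 at 5 Mbp).
#' @param set_size total size of the planted set; members beyond
#'   `n_members` are scattered over background genes so the set passes the
#'   size floor while keeping the island dominant (default 15).
#' @return list understood by [simulate_genome()].
#' @export
island_spec <- function(set = 1L, n_members = 12L, n_genes = 15L,
                        chrom = "chr1", start = 5e6, set_size = 15L) {
  stopifnot(n_members >= 1L, n_genes >= n_members, set_size >= n_members)
  list(set = as.integer(set), n_members = as.integer(n_members),
       n_genes = as.integer(n_genes), chrom = chrom, start = start,
       set_size = as.integer(set_size))
}

#' Specify a planted copy-number alteration
#'
#' @param chrom,start,end altered interval.
#' @param carrier_fraction probability a sample carries the alteration
#'   (default 0.4).
#' @param mean_log2 mean segment log2 ratio for carriers — positive for a
#'   gain, negative for a loss (default +0.5).
#' @param sd_log2 carrier log2 standard deviation (default 0.1).
#' @return list understood by [simulate_cohort()].
#' @export
cna_alteration <- function(chrom, start, end, carrier_fraction = 0.4,
                           mean_log2 = 0.5, sd_log2 = 0.1) {
  stopifnot(start < end, carrier_fraction >= 0, carrier_fraction <= 1)
  list(chrom = chrom, start = start, end = end,
       carrier_fraction = carrier_fraction,
       mean_log2 = mean_log2, sd_log2 = sd_log2)
}

#' Simulate a cohort of segment calls and survival outcomes
#'
#' Each sample receives every planted alteration independently with its
#' carrier probability; carrier segments draw their log2 ratio from the
#' alteration's normal, everything else is near-diploid noise. Chromosomes
#' are split at a few random breakpoints to mimic segmented (CBS-style)
#' output. Survival times are exponential with the hazard multiplied by
#' `hazard_ratio` per carried alteration (a proportional-hazards effect);
#' censoring times are uniform on (0, u) with u calibrated so the expected
#' non-carrier censoring proportion matches `censoring`.
#'
#' @param catalog a [gene_catalog()] supplying chromosome names/lengths.
#' @param alterations list of [cna_alteration()] specifications (default
#'   none: a null cohort).
#' @param n_samples cohort size (default 76).
#' @param noise_sd log2 standard deviation of unaltered segments (default 0.05).
#' @param breaks_per_chrom random extra breakpoints per chromosome (default 2).
#' @param baseline_hazard events per time unit for non-carriers
#'   (default 0.03, i.e. median survival ~23 time units).
#' @param hazard_ratio hazard multiplier per carried alteration (default 2).
#' @param censoring target censoring proportion in \[0, 1) (default 0.3).
#' @param seed integer seed, or `NULL`.
#' @return list with `segments` (a `cna_segments` table), `survival`
#'   (`sample`, `time`, `event`), and `truth` (`sample` x alteration carrier
#'   indicator matrix).
#' @export
simulate_cohort <- function(catalog, alterations = list(), n_samples = 76,
                            noise_sd = 0.05, breaks_per_chrom = 2L,
                            baseline_hazard = 0.03, hazard_ratio = 2,
                            censoring = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cl <- chrom_lengths(catalog)
  samples <- sprintf("S%03d", seq_len(n_samples))
  carrier <- matrix(FALSE, n_samples, length(alterations),
                    dimnames = list(samples, NULL))
  for (a in seq_along(alterations))
    carrier[, a] <- stats::runif(n_samples) < alterations[[a]]$carrier_fraction

  seg_rows <- list()
  for (s in seq_len(n_samples)) {
    for (chrom in names(cl)) {
      L <- cl[[chrom]]
      cuts <- sort(unique(round(stats::runif(breaks_per_chrom, 0, L))))
      alts_here <- which(vapply(alterations, function(a)
        a$chrom == chrom, TRUE) & carrier[s, ])
      for (a in alts_here)
        cuts <- c(cuts, alterations[[a]]$start, alterations[[a]]$end)
      bp <- sort(unique(c(0, cuts, L)))
      bp <- bp[bp >= 0 & bp <= L]
      st <- bp[-length(bp)]; en <- bp[-1L]
      mid <- (st + en) / 2
      log2 <- stats::rnorm(length(st), 0, noise_sd)
      for (a in alts_here) {
        inside <- mid >= alterations[[a]]$start & mid < alterations[[a]]$end
        log2[inside] <- stats::rnorm(sum(inside), alterations[[a]]$mean_log2,
                                     alterations[[a]]$sd_log2)
      }
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        sample = samples[s], chrom = chrom, start = st, end = en,
        log2 = round(log2, 6), stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, seg_rows)
  segments <- segments[order(segments$sample, segments$chrom, segments$start), ,
                       drop = FALSE]
  rownames(segments) <- NULL
  class(segments) <- c("cna_segments", "data.frame")

  hz <- baseline_hazard * hazard_ratio^rowSums(carrier)
  t_event <- stats::rexp(n_samples, rate = hz)
  if (censoring > 0) {
    u <- .censor_horizon(baseline_hazard, censoring)
    t_cens <- stats::runif(n_samples, 0, u)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n_samples)
  }
  survival <- data.frame(sample = samples, time = round(time, 4),
                         event = event, stringsAsFactors = FALSE)
  list(segments = segments, survival = survival, truth = carrier)
}

# horizon u with E[P(Unif(0,u) < Exp(h))] = target censoring proportion
.censor_horizon <- function(h, target) {
  stopifnot(target > 0, target < 1)
  f <- function(u) (1 - exp(-h * u)) / (h * u) - target
  stats::uniroot(f, lower = 1e-9 / h, upper = 1e6 / h, tol = 1e-10)$root
}
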