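#' Upper-tail hypergeometric probability
#'
#' The enrichment score of a genomic segment against a gene set: the
#' probability of drawing at least `z` annotated genes when `x` genes are
#' sampled without replacement from a genome of `M` genes of which `y` carry
#' the annotation,
#' \deqn{P(X \ge z) = \sum_{h=z}^{\min(x,y)} \binom{y}{h}\binom{M-y}{x-h} \big/ \binom{M}{x},}
#' i.e. the one-sided Fisher exact test of the 2x2 overlap table. Evaluated
#' through [stats::phyper()], which works in log space, so genome-scale `M`
#' does not overflow. Vectorized over all arguments.
#'
#' @param M genome size (number of genes).
#' @param x number of genes in the segment.
#' @param y number of genes in the set.
#' @param z observed overlap.
#' @return Probability in (0, 1]; `z = 0` returns exactly 1.
#' @examples
#' hypergeom_upper_tail(10, 4, 5, 4)  # 5/210
#' @export
hypergeom_upper_tail <- function(M, x, y, z) {
  n <- max(length(M), length(x), length(y), length(z))
  M <- rep_len(as.numeric(M), n); x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n); z <- rep_len(as.numeric(z), n)
  if (anyNA(c(M, x, y, z)))
    stop("hypergeometric arguments must be non-missing")
  if (any(x < 0 | y < 0 | z < 0 | x > M | y > M | z > pmin(x, y)))
    stop("hypergeometric bounds violated: need 0 <= z <= min(x, y) <= M")
  p <- ifelse(z <= 0, 1,
              stats::phyper(z - 1, m = y, n = M - y, k = x, lower.tail = FALSE))
  pmax(pmin(p, 1), .Machine$double.xmin)
}

#' Build the window and set indicator matrices
#'
#' Constructs the two sparse binary matrices driving the scan: `B` (windows x
#' genes; `b[k, i] = 1` when gene i starts inside window k) and `P` (genes x
#' sets; `p[i, l] = 1` when gene i belongs to set l). Row sums of `B` are the
#' per-window gene counts `x_k`; column sums of `P` are the set sizes `y_l`.
#'
#' @param catalog a [gene_catalog()].
#' @param windows a [build_windows()] tiling of the same catalog.
#' @param sets a [gene_sets()] collection resolved against the same catalog.
#' @return An `indicator_context`: list with sparse matrices `B`, `P`,
#'   dimensions `M`, `K`, `L`, and the input `catalog`, `windows`, `sets`.
#' @export
build_indicators <- function(catalog, windows, sets) {
  if (!NROW(windows)) stop("empty window collection")
  if (!NROW(sets)) stop("empty gene-set collection")
  M <- nrow(catalog); K <- nrow(windows); L <- nrow(sets)
  B <- Matrix::sparseMatrix(i = rep.int(seq_len(K), lengths(windows$genes)),
                            j = unlist(windows$genes),
                            x = 1, dims = c(K, M))
  if (any(Matrix::colSums(B) == 0))
    stop("catalog gene(s) fall in no window; the tiling does not cover the catalog")
  idx <- lapply(sets$members, match, table = catalog$gene_id)
  if (anyNA(unlist(idx)))
    stop("set member(s) not resolvable to catalog indices")
  P <- Matrix::sparseMatrix(i = unlist(idx),
                            j = rep.int(seq_len(L), lengths(idx)),
                            x = 1, dims = c(M, L))
  structure(list(B = B, P = P, M = M, K = K, L = L,
                 catalog = catalog, windows = windows, sets = sets),
            class = "indicator_context")
}

#' @export
print.indicator_context <- function(x, ...) {
  cat("Indicator context: K =", x$K, "windows, M =", x$M, "genes, L =",
      x$L, "sets\n")
  invisible(x)
}

#' Score every window x gene-set pair
#'
#' Computes the overlap `z[k, l]` for every window/set pair via a sparse
#' matrix product, evaluates the upper-tail hypergeometric p for every pair
#' with positive overlap (pairs with `z = 0` have p = 1 and are not
#' materialized), and applies Bonferroni control with the adjustment factor
#' `T` equal to the number of tests actually performed, i.e. the number of
#' materialized cells. `T` is returned so a stricter `K*L` family can be
#' recomputed by the caller.
#'
#' @param ctx an [build_indicators()] context.
#' @param alpha family-wise significance level (default 0.05).
#' @param adjust multiplicity adjustment; only `"bonferroni"`.
#' @return An `sfh_cells` data.frame (one row per pair with `z > 0`):
#'   `window`, `set`, `chrom`, `win_start`, `win_end`, `set_id`, `x`, `y`,
#'   `z`, `p`, `p_adj`, `enriched`; attributes `n_tests` and `alpha`.
#' @export
scan_windows <- function(ctx, alpha = 0.05, adjust = c("bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(ctx, "indicator_context"))
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must lie in (0, 1)")
  Z <- methods::as(ctx$B %*% ctx$P, "TsparseMatrix")
  i <- Z@i + 1L; j <- Z@j + 1L; z <- Z@x
  pos <- z > 0
  i <- i[pos]; j <- j[pos]; z <- z[pos]
  xk <- Matrix::rowSums(ctx$B)
  yl <- Matrix::colSums(ctx$P)
  n_tests <- length(z)
  p <- hypergeom_upper_tail(ctx$M, xk[i], yl[j], z)
  p_adj <- pmin(1, p * n_tests)
  cells <- data.frame(window = i, set = j,
                      chrom = ctx$windows$chrom[i],
                      win_start = ctx$windows$start[i],
                      win_end = ctx$windows$end[i],
                      set_id = ctx$sets$set_id[j],
                      x = xk[i], y = yl[j], z = z,
                      p = p, p_adj = p_adj,
                      enriched = p_adj < alpha,
                      stringsAsFactors = FALSE)
  cells <- cells[order(cells$set, cells$window), , drop = FALSE]
  rownames(cells) <- NULL
  structure(cells, n_tests = n_tests, alpha = alpha,
            class = c("sfh_cells", "data.frame"))
}
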