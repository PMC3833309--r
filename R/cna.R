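#' Read per-sample copy-number segment calls (SEG)
#'
#' Tab-delimited CBS-style output: sample, chromosome, start, end, an
#' optional marker-count column, and the segment mean log2 ratio as the last
#' column. A header line is tolerated and detected by non-numeric
#' coordinates. Segments are returned sorted within sample and chromosome;
#' overlapping segments within one sample (which CBS should never emit) are
#' reported with a warning.
#'
#' @param path SEG file path.
#' @return A `cna_segments` data.frame: `sample`, `chrom`, `start`, `end`,
#'   `log2`.
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty SEG file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L))
    stop("malformed SEG line ", lineno[which(nf < 5L)[1L]],
         ": expected at least 5 tab-separated fields")
  # header detection: first line with non-numeric start coordinate
  if (is.na(suppressWarnings(as.numeric(fields[[1L]][3L])))) {
    fields <- fields[-1L]; lineno <- lineno[-1L]
    if (!length(fields)) stop("empty SEG file: ", path)
  }
  grab <- function(k) vapply(fields, `[[`, "", k)
  start <- suppressWarnings(as.numeric(grab(3L)))
  end <- suppressWarnings(as.numeric(grab(4L)))
  log2 <- suppressWarnings(as.numeric(vapply(fields, function(f) f[[length(f)]], "")))
  for (v in list(start = start, end = end)) {
    if (anyNA(v))
      stop("non-numeric coordinate at SEG line ", lineno[which(is.na(v))[1L]])
  }
  if (anyNA(log2))
    stop("non-numeric log2 segment mean at SEG line ", lineno[which(is.na(log2))[1L]])
  if (any(start >= end))
    stop("segment start must be < end at SEG line ", lineno[which(start >= end)[1L]])
  seg <- data.frame(sample = grab(1L), chrom = grab(2L),
                    start = start, end = end, log2 = log2,
                    stringsAsFactors = FALSE)
  seg <- seg[order(seg$sample, seg$chrom, seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  n_overlap <- sum(vapply(split(seg, list(seg$sample, seg$chrom), drop = TRUE),
                          function(s) sum(s$start[-1L] < s$end[-nrow(s)]), 0L))
  if (n_overlap > 0L)
    warning(n_overlap, " overlapping segment pair(s) within a sample")
  structure(seg, class = c("cna_segments", "data.frame"))
}

#' Write segment calls as SEG
#' @param segments a `cna_segments` data.frame (see [read_seg()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  out <- c("sample\tchrom\tstart\tend\tseg.mean",
           sprintf("%s\t%s\t%s\t%s\t%s", segments$sample, segments$chrom,
                   format(segments$start, scientific = FALSE, trim = TRUE),
                   format(segments$end, scientific = FALSE, trim = TRUE),
                   format(segments$log2, scientific = FALSE, trim = TRUE,
                          digits = 15)))
  writeLines(out, path)
  invisible(path)
}

#' Classify each hotspot per sample as gain / loss / neutral
#'
#' For every sample and hotspot, the hotspot bases overlapped by segments
#' with log2 ratio above `gain_thr` are counted as gain-bp and below
#' `loss_thr` as loss-bp (the conventional +/- 0.2 log2 cutoffs by default).
#' The per-sample status is the majority call: gain when gain-bp exceeds
#' loss-bp (and is positive), loss symmetrically, neutral otherwise. An
#' exact positive tie is neutral and flagged `ambiguous`; a hotspot
#' chromosome absent from a sample's segments yields neutral, flagged
#' `uncovered`. Both overlap counts are reported so any other status rule
#' can be recomputed.
#'
#' @param hotspots an [sfh_detect()] fit, an `sfh_hotspots` table, or any
#'   data.frame with columns `chrom`, `start`, `end` (and optionally
#'   `hotspot_id`).
#' @param segments a `cna_segments` table from [read_seg()] or
#'   [simulate_cohort()].
#' @param gain_thr log2 threshold for gain (default `0.2`; must be > 0).
#' @param loss_thr log2 threshold for loss (default `-0.2`; must be < 0).
#' @return A `cna_status` data.frame: `sample`, `hotspot_id`, `status`
#'   (factor gain/loss/neutral), `gain_bp`, `loss_bp`, `ambiguous`,
#'   `uncovered`; attribute `samples`.
#' @export
classify_cna_status <- function(hotspots, segments, gain_thr = 0.2,
                                loss_thr = -0.2) {
  if (!(gain_thr > 0) || !(loss_thr < 0))
    stop("need gain_thr > 0 > loss_thr")
  h <- .hotspot_frame(hotspots)
  samples <- unique(segments$sample)
  if (!length(samples)) stop("no samples in segment table")
  seg_by_sample <- split(segments, segments$sample)
  rows <- vector("list", length(samples) * nrow(h))
  k <- 0L
  n_uncov <- 0L
  for (s in samples) {
    seg <- seg_by_sample[[s]]
    for (i in seq_len(nrow(h))) {
      on <- seg[seg$chrom == h$chrom[i], , drop = FALSE]
      uncovered <- nrow(on) == 0L
      if (uncovered) {
        gain_bp <- loss_bp <- 0
        n_uncov <- n_uncov + 1L
      } else {
        ov <- pmax(0, pmin(on$end, h$end[i]) - pmax(on$start, h$start[i]))
        gain_bp <- sum(ov[on$log2 > gain_thr])
        loss_bp <- sum(ov[on$log2 < loss_thr])
      }
      status <- if (gain_bp > loss_bp && gain_bp > 0) "gain"
                else if (loss_bp > gain_bp && loss_bp > 0) "loss"
                else "neutral"
      k <- k + 1L
      rows[[k]] <- data.frame(sample = s, hotspot_id = h$hotspot_id[i],
                              status = status, gain_bp = gain_bp,
                              loss_bp = loss_bp,
                              ambiguous = gain_bp == loss_bp && gain_bp > 0,
                              uncovered = uncovered,
                              stringsAsFactors = FALSE)
    }
  }
  if (n_uncov)
    message(n_uncov, " (sample, hotspot) pair(s) had no segments on the ",
            "hotspot chromosome; counted neutral")
  out <- do.call(rbind, rows)
  out$status <- factor(out$status, levels = c("gain", "loss", "neutral"))
  rownames(out) <- NULL
  structure(out, samples = samples, gain_thr = gain_thr, loss_thr = loss_thr,
            class = c("cna_status", "data.frame"))
}

.hotspot_frame <- function(hotspots) {
  h <- if (inherits(hotspots, "sfh")) hotspots$hotspots else hotspots
  h <- as.data.frame(h)
  if (!nrow(h)) stop("no hotspots to classify")
  if (!"hotspot_id" %in% names(h))
    h$hotspot_id <- if (all(c("set_id", "chrom", "start") %in% names(h)))
      sprintf("%s:%s:%s", h$set_id, h$chrom,
              format(h$start, scientific = FALSE, trim = TRUE))
    else sprintf("hotspot_%03d", seq_len(nrow(h)))
  if (anyDuplicated(h$hotspot_id)) stop("hotspot ids are not unique")
  h[c("hotspot_id", "chrom", "start", "end")]
}

#' Recurrently altered hotspots across a cohort
#'
#' Counts, per hotspot, the samples called gain and loss, converts to cohort
#' fractions, and flags recurrence when the fraction strictly exceeds
#' `min_fraction` (default 0.30, i.e. "altered in more than 30% of
#' patients"). Records are sorted by the larger of the two counts,
#' descending.
#'
#' @param status a [classify_cna_status()] table.
#' @param min_fraction strict recurrence cutoff in (0, 1) (default 0.30).
#' @return A `cna_recurrence` data.frame: `hotspot_id`, `n_gain`, `n_loss`,
#'   `frac_gain`, `frac_loss`, `recurrent_gain`, `recurrent_loss`; attribute
#'   `n_samples`.
#' @export
cna_recurrence <- function(status, min_fraction = 0.30) {
  if (!(min_fraction > 0 && min_fraction < 1))
    stop("`min_fraction` must lie in (0, 1)")
  n_samples <- length(attr(status, "samples") %||% unique(status$sample))
  tab <- table(status$hotspot_id, status$status)
  out <- data.frame(hotspot_id = rownames(tab),
                    n_gain = as.integer(tab[, "gain"]),
                    n_loss = as.integer(tab[, "loss"]),
                    stringsAsFactors = FALSE)
  out$frac_gain <- out$n_gain / n_samples
  out$frac_loss <- out$n_loss / n_samples
  out$recurrent_gain <- out$frac_gain > min_fraction
  out$recurrent_loss <- out$frac_loss > min_fraction
  out <- out[order(-pmax(out$n_gain, out$n_loss), out$hotspot_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_samples = n_samples, min_fraction = min_fraction,
            class = c("cna_recurrence", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Copy-number overlay of a hotspot scan
#'
#' Convenience wrapper: classifies every hotspot in every sample and screens
#' for recurrence, returning both tables together with a hotspot x sample
#' status matrix.
#'
#' @inheritParams classify_cna_status
#' @inheritParams cna_recurrence
#' @return An object of class `"sfh_cna"`: list with `status` (long table),
#'   `status_matrix` (hotspot x sample), `recurrence`, `params`.
#' @export
sfh_cna <- function(hotspots, segments, gain_thr = 0.2, loss_thr = -0.2,
                    min_fraction = 0.30) {
  status <- classify_cna_status(hotspots, segments, gain_thr, loss_thr)
  rec <- cna_recurrence(status, min_fraction)
  mat <- tapply(as.character(status$status),
                list(status$hotspot_id, status$sample), identity)
  structure(list(status = status, status_matrix = mat, recurrence = rec,
                 params = list(gain_thr = gain_thr, loss_thr = loss_thr,
                               min_fraction = min_fraction)),
            class = "sfh_cna")
}

#' @export
print.sfh_cna <- function(x, ...) {
  rec <- x$recurrence
  cat("Hotspot copy-number overlay:", nrow(rec), "hotspot(s) x",
      attr(rec, "n_samples"), "sample(s)\n")
  cat("  recurrent (fraction > ", attr(rec, "min_fraction"), "): gain ",
      sum(rec$recurrent_gain), ", loss ", sum(rec$recurrent_loss), "\n", sep = "")
  print(utils::head(rec, 5L))
  invisible(x)
}
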