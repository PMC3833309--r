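#' Two-group log-rank test
#'
#' The standard log-rank statistic computed from first principles: at every
#' distinct event time the observed number of events in group 1 is compared
#' with its expectation under the pooled risk set, with the multi-death
#' hypergeometric variance term `d (n1/n) (1 - n1/n) (n - d) / (n - 1)`, and
#' the squared standardized sum is referred to the 1-df chi-square upper
#' tail.
#'
#' @param time non-negative follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param group two-level grouping (anything coercible to a factor with two
#'   observed levels).
#' @return A list of class `logrank_test`: `chi_square`, `p_value`,
#'   `observed`, `expected` (group-1 totals), `n1`, `n2`, `n_events`.
#' @examples
#' logrank_test(time = c(1, 2, 3, 4), event = rep(1, 4),
#'              group = c("A", "A", "B", "B"))  # chi-square = 49/17
#' @export
logrank_test <- function(time, event, group) {
  time <- as.numeric(time); event <- as.integer(event)
  group <- factor(group)
  if (length(unique(c(length(time), length(event), length(group)))) != 1L)
    stop("time, event and group must have equal length")
  if (anyNA(time) || anyNA(event) || anyNA(group)) stop("missing values")
  if (any(time < 0)) stop("negative follow-up time")
  lev <- levels(droplevels(group))
  if (length(lev) != 2L) stop("exactly two non-empty groups are required")
  if (sum(event) < 1L) stop("no events in either group; the test carries no information")
  g1 <- group == lev[1L]
  ev_times <- sort(unique(time[event == 1L]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1L) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  structure(list(chi_square = chi,
                 p_value = if (V > 0) stats::pchisq(chi, df = 1, lower.tail = FALSE) else 1,
                 observed = O, expected = E,
                 n1 = sum(g1), n2 = sum(!g1), n_events = sum(event),
                 groups = lev),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test: ", x$groups[1L], " (n=", x$n1, ") vs ", x$groups[2L],
      " (n=", x$n2, ")\n", sep = "")
  cat("  observed/expected in group 1: ", x$observed, " / ",
      round(x$expected, 3), "\n", sep = "")
  cat("  chi-square = ", format(x$chi_square, digits = 6),
      " (1 df), p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate. With no censoring the estimate equals the
#' empirical survival function.
#'
#' @inheritParams logrank_test
#' @return data.frame: `time`, `n_risk`, `n_event`, `survival` (one row per
#'   distinct event time, prepended with time 0 / survival 1).
#' @export
km_curve <- function(time, event) {
  time <- as.numeric(time); event <- as.integer(event)
  ev_times <- sort(unique(time[event == 1L]))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), 0)
  n_event <- vapply(ev_times, function(t) sum(time == t & event == 1L), 0)
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = c(0, ev_times), n_risk = c(length(time), n_risk),
             n_event = c(0, n_event), survival = c(1, surv))
}

#' Read a survival table
#' @param path tab-delimited file with header: sample_id, time, event.
#' @return data.frame `sample`, `time`, `event`.
#' @export
read_survival <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("survival table needs columns sample_id, time, event")
  out <- data.frame(sample = as.character(tab[[1L]]),
                    time = as.numeric(tab[[2L]]),
                    event = as.integer(tab[[3L]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$time) || any(out$time < 0)) stop("times must be non-negative numbers")
  if (!all(out$event %in% c(0L, 1L))) stop("event must be 0 (censored) or 1 (event)")
  out
}

#' Write a survival table
#' @param survival data.frame `sample`, `time`, `event`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_survival <- function(survival, path) {
  out <- c("sample_id\ttime\tevent",
           sprintf("%s\t%s\t%d", survival$sample,
                   format(survival$time, scientific = FALSE, trim = TRUE,
                          digits = 15),
                   as.integer(survival$event)))
  writeLines(out, path)
  invisible(path)
}

#' Screen hotspot copy-number status against survival
#'
#' For every hotspot, two independent two-group log-rank contrasts are run:
#' gain versus neutral (loss samples excluded) and loss versus neutral (gain
#' samples excluded). Contrasts with fewer than `min_group` samples in
#' either arm, or with no events, are skipped and counted. No multiplicity
#' correction is applied; the number of tests performed is reported so the
#' caller can adjust post hoc.
#'
#' @param status a [classify_cna_status()] table (or an [sfh_cna()] object).
#' @param survival a survival table (`sample`, `time`, `event`), e.g. from
#'   [read_survival()] or [simulate_cohort()].
#' @param alpha raw significance cutoff (default 0.01).
#' @param min_group minimum samples per arm (default 3).
#' @return An object of class `sfh_survscreen`: list with `results`
#'   (data.frame `hotspot_id`, `contrast`, `n_altered`, `n_neutral`,
#'   `chi_square`, `p_value`, `significant`), `n_tests`, `n_skipped`,
#'   `alpha`, plus the merged `data` for Kaplan-Meier export via
#'   [km_export()].
#' @export
survival_screen <- function(status, survival, alpha = 0.01, min_group = 3L) {
  if (inherits(status, "sfh_cna")) status <- status$status
  common <- intersect(unique(status$sample), survival$sample)
  n_miss <- length(unique(status$sample)) - length(common)
  if (n_miss > 0L)
    message(n_miss, " sample(s) without survival record dropped from the screen")
  if (!length(common)) stop("no overlap between CNA cohort and survival table")
  surv <- survival[match(common, survival$sample), , drop = FALSE]
  status <- status[status$sample %in% common, , drop = FALSE]
  dat <- merge(status[c("sample", "hotspot_id", "status")], surv, by = "sample")

  rows <- list(); n_skipped <- 0L
  for (hs in split(dat, dat$hotspot_id)) {
    for (alt in c("gain", "loss")) {
      sub <- hs[hs$status %in% c(alt, "neutral"), , drop = FALSE]
      n_alt <- sum(sub$status == alt)
      n_neu <- sum(sub$status == "neutral")
      if (n_alt < min_group || n_neu < min_group || sum(sub$event) < 1L) {
        n_skipped <- n_skipped + (n_alt > 0L)  # only count contrasts that existed
        next
      }
      lr <- logrank_test(sub$time, sub$event,
                         factor(sub$status == alt, levels = c(TRUE, FALSE),
                                labels = c(alt, "neutral")))
      rows[[length(rows) + 1L]] <- data.frame(
        hotspot_id = hs$hotspot_id[1L],
        contrast = paste0(alt, "_vs_neutral"),
        n_altered = n_alt, n_neutral = n_neu,
        chi_square = lr$chi_square, p_value = lr$p_value,
        significant = lr$p_value < alpha,
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hotspot_id = character(), contrast = character(),
               n_altered = integer(), n_neutral = integer(),
               chi_square = numeric(), p_value = numeric(),
               significant = logical(), stringsAsFactors = FALSE)
  results <- results[order(results$p_value), , drop = FALSE]
  rownames(results) <- NULL
  if (n_skipped)
    message(n_skipped, " contrast(s) skipped (undersized group or no events)")
  structure(list(results = results, n_tests = nrow(results),
                 n_skipped = n_skipped, alpha = alpha, data = dat),
            class = "sfh_survscreen")
}

#' @export
print.sfh_survscreen <- function(x, ...) {
  cat("Survival screen:", x$n_tests, "log-rank contrast(s), ",
      sum(x$results$significant), "significant at p <", x$alpha, "\n")
  print(utils::head(x$results, 8L))
  invisible(x)
}

#' Export Kaplan-Meier step functions for one contrast
#'
#' @param screen an [survival_screen()] object.
#' @param hotspot_id hotspot to export.
#' @param contrast `"gain_vs_neutral"` or `"loss_vs_neutral"`.
#' @return data.frame `time`, `survival`, `group` stacking the two
#'   product-limit curves.
#' @export
km_export <- function(screen, hotspot_id,
                      contrast = c("gain_vs_neutral", "loss_vs_neutral")) {
  contrast <- match.arg(contrast)
  alt <- sub("_vs_neutral", "", contrast)
  dat <- screen$data
  dat <- dat[dat$hotspot_id == hotspot_id & dat$status %in% c(alt, "neutral"), ,
             drop = FALSE]
  if (!nrow(dat)) stop("no samples for hotspot ", hotspot_id)
  do.call(rbind, lapply(c(alt, "neutral"), function(g) {
    sub <- dat[dat$status == g, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    cbind(km_curve(sub$time, sub$event)[c("time", "survival")], group = g)
  }))
}
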