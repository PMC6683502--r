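#' Match called CNV events against a truth set
#'
#' A called event matches a truth event when the two share the sample, the
#' CNV type, and at least 1 bp of overlap between the call's maximum span
#' and the truth interval.  Unmatched truth events are `undetected`;
#' unmatched calls are `false_positive`.  One truth event overlapped by
#' several calls is a `split` link; several truth events overlapped by one
#' call are a `merged` link.
#'
#' @param gbs A call table with columns `sample`, `type`, `chrom`,
#'   `max_start`, `max_end` (and `min_start`, `min_end` for downstream size
#'   statistics), e.g. a `cnv_calls` object.
#' @param truth A truth table with columns `sample`, `type`, `chrom`,
#'   `start`, `end` (0-based half-open), e.g. from [load_truth_table()] or a
#'   simulator truth table.
#' @return An object of class `match_result`: list with `gbs` and `truth`
#'   (copies with a `status` column and the matched counterpart indices),
#'   `links` (data.frame `gbs_idx`, `truth_idx`, `relation`), and counts
#'   `n_true_positive`, `n_false_positive`, `n_detected`, `n_undetected`.
#' @export
match_events <- function(gbs, truth) {
  gbs <- as.data.frame(gbs)
  truth <- as.data.frame(truth)
  key <- function(df) paste(df$sample, df$type, df$chrom, sep = "|")
  if (nrow(gbs) > 0 && nrow(truth) > 0) {
    lev <- union(key(gbs), key(truth))
    gr_g <- GenomicRanges::GRanges(factor(key(gbs), lev),
      IRanges::IRanges(gbs$max_start + 1, pmax(gbs$max_end, gbs$max_start + 1)))
    gr_t <- GenomicRanges::GRanges(factor(key(truth), lev),
      IRanges::IRanges(truth$start + 1, pmax(truth$end, truth$start + 1)))
    ov <- GenomicRanges::findOverlaps(gr_g, gr_t)
    links <- data.frame(gbs_idx = S4Vectors::queryHits(ov),
                        truth_idx = S4Vectors::subjectHits(ov))
  } else {
    links <- data.frame(gbs_idx = integer(), truth_idx = integer())
  }
  g_deg <- tabulate(links$gbs_idx, nbins = nrow(gbs))
  t_deg <- tabulate(links$truth_idx, nbins = nrow(truth))
  links$relation <- ifelse(t_deg[links$truth_idx] > 1, "split",
                           ifelse(g_deg[links$gbs_idx] > 1, "merged",
                                  "one_to_one"))
  gbs$status <- ifelse(g_deg > 0, "true_positive", "false_positive")
  truth$status <- ifelse(t_deg > 0, "detected", "undetected")
  structure(list(gbs = gbs, truth = truth, links = links,
                 n_true_positive = sum(g_deg > 0),
                 n_false_positive = sum(g_deg == 0),
                 n_detected = sum(t_deg > 0),
                 n_undetected = sum(t_deg == 0)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("match_result:", nrow(x$gbs), "calls vs", nrow(x$truth), "truth events\n",
      " true positives:", x$n_true_positive,
      " false positives:", x$n_false_positive, "\n",
      " detected:", x$n_detected, " undetected:", x$n_undetected, "\n")
  invisible(x)
}

#' Size-agreement statistics for one-to-one matched homozygous deletions
#'
#' For matched pairs with a one-to-one correspondence (split and merged
#' events excluded), computes the mean minimum- and maximum-span lengths as
#' percentages of the truth-estimated size, and the adjusted R-squared of an
#' ordinary least-squares fit of log10(truth size) on log10(minimum span)
#' and log10(maximum span).
#'
#' @param match A [match_events()] result.
#' @param type CNV type to evaluate (default `"homdel"`).
#' @return List with `mean_min_pct`, `mean_max_pct`, `adj_r2` (`NA` when
#'   fewer than 4 pairs), and `n`.
#' @export
size_agreement <- function(match, type = "homdel") {
  stopifnot(inherits(match, "match_result"))
  lk <- match$links[match$links$relation == "one_to_one", , drop = FALSE]
  if (nrow(lk) > 0)
    lk <- lk[match$gbs$type[lk$gbs_idx] == type, , drop = FALSE]
  if (nrow(lk) == 0)
    return(list(mean_min_pct = NA_real_, mean_max_pct = NA_real_,
                adj_r2 = NA_real_, n = 0L))
  g <- match$gbs[lk$gbs_idx, , drop = FALSE]
  t <- match$truth[lk$truth_idx, , drop = FALSE]
  truth_size <- t$end - t$start
  min_len <- g$min_end - g$min_start
  max_len <- g$max_end - g$max_start
  ok <- truth_size > 0 & min_len > 0 & max_len > 0
  g <- g[ok, ]; truth_size <- truth_size[ok]
  min_len <- min_len[ok]; max_len <- max_len[ok]
  n <- length(truth_size)
  if (n == 0)
    return(list(mean_min_pct = NA_real_, mean_max_pct = NA_real_,
                adj_r2 = NA_real_, n = 0L))
  adj_r2 <- if (n >= 4) {
    fit <- lm(log10(truth_size) ~ log10(min_len) + log10(max_len))
    summary(fit)$adj.r.squared
  } else NA_real_
  list(mean_min_pct = mean(100 * min_len / truth_size),
       mean_max_pct = mean(100 * max_len / truth_size),
       adj_r2 = adj_r2, n = n)
}

#' Detection counts per CNV type and size class
#'
#' Tabulates truth events as detected/undetected within size classes, and
#' reports the smallest detected and largest undetected truth size per type.
#'
#' @param match A [match_events()] result.
#' @param breaks_kbp Size-class boundaries in kbp.
#' @return List with `table` (type x size class x status counts) and
#'   `extremes` (per type: `smallest_detected_kbp`,
#'   `largest_undetected_kbp`, `NA` when empty).
#' @export
detection_by_size <- function(match, breaks_kbp = c(0, 10, 30, 60, 100, 250,
                                                    500, 1000, Inf)) {
  stopifnot(inherits(match, "match_result"))
  tr <- match$truth
  size_kbp <- (tr$end - tr$start) / 1000
  cls <- cut(size_kbp, breaks = breaks_kbp, include.lowest = TRUE)
  tab <- table(type = tr$type, size = cls,
               status = factor(tr$status,
                               levels = c("detected", "undetected")))
  extremes <- lapply(split(seq_len(nrow(tr)), tr$type), function(ix) {
    det <- size_kbp[ix][tr$status[ix] == "detected"]
    und <- size_kbp[ix][tr$status[ix] == "undetected"]
    list(smallest_detected_kbp = if (length(det)) min(det) else NA_real_,
         largest_undetected_kbp = if (length(und)) max(und) else NA_real_)
  })
  list(table = tab, extremes = extremes)
}

#' Count gene models affected per CNV type
#'
#' Counts gene models overlapping each event by at least 1 bp (over the
#' event's minimum span by default) and tallies them by CNV type.  A gene
#' hit by events in several lines counts once per event, so the totals
#' reflect gene disruptions, not distinct genes.
#'
#' @param calls Call table with span columns.
#' @param genes A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `id`.
#' @param span `"min"` (default) or `"max"`: which event span to overlap.
#' @return Named numeric vector of totals per type (`homdel`, `hetdel`,
#'   `dup`).
#' @export
count_affected_genes <- function(calls, genes, span = c("min", "max")) {
  span <- match.arg(span)
  totals <- c(homdel = 0, hetdel = 0, dup = 0)
  if (nrow(calls) == 0 || nrow(genes) == 0) return(totals)
  if (any(genes$end <= genes$start)) stop("gene intervals must have end > start")
  s <- if (span == "min") calls$min_start else calls$max_start
  e <- if (span == "min") calls$min_end else calls$max_end
  lev <- union(unique(calls$chrom), unique(genes$chrom))
  gr_c <- GenomicRanges::GRanges(factor(calls$chrom, lev),
                                 IRanges::IRanges(s + 1, pmax(e, s + 1)))
  gr_g <- GenomicRanges::GRanges(factor(genes$chrom, lev),
                                 IRanges::IRanges(genes$start + 1, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_c, gr_g)
  hits <- table(calls$type[S4Vectors::queryHits(ov)])
  totals[names(hits)] <- as.numeric(hits)
  totals
}
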