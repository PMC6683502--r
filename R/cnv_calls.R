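#' CNV classification thresholds and support minima
#'
#' A segment becomes a homozygous-deletion candidate when its mean log2 ratio
#' is strictly below `homdel_max`, a hemizygous deletion when the mean lies in
#' the closed interval `[hetdel_min, hetdel_max]`, and a duplication when the
#' mean is strictly above `dup_min`; means in `(hetdel_max, dup_min]` are
#' copy-neutral.  Candidates survive the support filter when backed by at
#' least `min_bins_homdel` (homozygous deletions) or `min_bins_hetdup`
#' (hemizygous deletions and duplications) informative bins.
#'
#' @param homdel_max,hetdel_min,hetdel_max,dup_min Log2-ratio boundaries.
#' @param min_bins_homdel,min_bins_hetdup Minimum supporting bins.
#' @return An object of class `class_thresholds`.
#' @export
class_thresholds <- function(homdel_max = -2.5, hetdel_min = -2.5,
                             hetdel_max = -0.5, dup_min = 0.2,
                             min_bins_homdel = 3, min_bins_hetdup = 6) {
  if (!(homdel_max <= hetdel_min && hetdel_min <= hetdel_max &&
        hetdel_max < dup_min))
    stop("need homdel_max <= hetdel_min <= hetdel_max < dup_min")
  if (min_bins_homdel < 1 || min_bins_hetdup < 1)
    stop("support minima must be >= 1")
  structure(list(homdel_max = homdel_max, hetdel_min = hetdel_min,
                 hetdel_max = hetdel_max, dup_min = dup_min,
                 min_bins_homdel = min_bins_homdel,
                 min_bins_hetdup = min_bins_hetdup),
            class = "class_thresholds")
}

.empty_calls <- function() {
  data.frame(sample = character(), type = character(), chrom = character(),
             first_bin = integer(), last_bin = integer(),
             n_bins = integer(), mean_log2 = numeric(),
             dataset = character(), stringsAsFactors = FALSE)
}

.classify_mean <- function(mean_log2, t) {
  ifelse(mean_log2 < t$homdel_max, "homdel",
         ifelse(mean_log2 >= t$hetdel_min & mean_log2 <= t$hetdel_max,
                "hetdel",
                ifelse(mean_log2 > t$dup_min, "dup", NA_character_)))
}

#' Classify segments into candidate CNV calls
#'
#' Maps every segment of a [segment_all()] result to at most one CNV type
#' using its arithmetic mean log2 ratio; copy-neutral segments yield no
#' candidate.  Bin indices in the result are positions within the
#' chromosome's informative-bin sequence.
#'
#' @param segs Result of [segment_all()].
#' @param t A [class_thresholds()].
#' @param dataset Label recorded on each call (e.g. `"mq20"`).
#' @return A candidate-call data.frame with columns `sample`, `type`,
#'   `chrom`, `first_bin`, `last_bin`, `n_bins`, `mean_log2`, `dataset`.
#' @export
classify_segments <- function(segs, t = class_thresholds(),
                              dataset = "mq20") {
  rows <- list()
  for (s in names(segs)) {
    for (ch in names(segs[[s]])) {
      sg <- segs[[s]][[ch]]
      type <- .classify_mean(sg$segment_means, t)
      keep <- which(!is.na(type))
      if (length(keep) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, type = type[keep], chrom = ch,
        first_bin = sg$starts[keep], last_bin = sg$ends[keep],
        n_bins = sg$ends[keep] - sg$starts[keep] + 1L,
        mean_log2 = sg$segment_means[keep], dataset = dataset,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(.empty_calls())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Discard calls with insufficient bin support
#'
#' Homozygous deletions need `min_bins_homdel` supporting informative bins,
#' hemizygous deletions and duplications `min_bins_hetdup`.
#'
#' @param calls Candidate-call data.frame.
#' @param t A [class_thresholds()].
#' @export
filter_support <- function(calls, t = class_thresholds()) {
  need <- ifelse(calls$type == "homdel", t$min_bins_homdel, t$min_bins_hetdup)
  calls[calls$n_bins >= need, , drop = FALSE]
}

#' Merge contiguous same-type calls
#'
#' Adjacent calls of the same sample, chromosome and type separated by no
#' intervening informative bin (i.e. whose supporting-bin index ranges are
#' consecutive) are merged into one event: bin counts are summed and the mean
#' log2 ratio is the bin-count-weighted mean.  A single intervening
#' informative bin -- copy-neutral or of another type -- breaks contiguity.
#'
#' @param calls Candidate-call data.frame, any order.
#' @export
merge_contiguous <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  o <- order(calls$sample, calls$chrom, calls$first_bin)
  calls <- calls[o, , drop = FALSE]
  out <- calls[0, , drop = FALSE]
  cur <- NULL
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, , drop = FALSE]
    if (!is.null(cur) &&
        cur$sample == row$sample && cur$chrom == row$chrom &&
        cur$type == row$type && cur$dataset == row$dataset &&
        row$first_bin == cur$last_bin + 1L) {
      w <- c(cur$n_bins, row$n_bins)
      cur$mean_log2 <- sum(w * c(cur$mean_log2, row$mean_log2)) / sum(w)
      cur$last_bin <- row$last_bin
      cur$n_bins <- cur$n_bins + row$n_bins
    } else {
      if (!is.null(cur)) out <- rbind(out, cur)
      cur <- row
    }
  }
  out <- rbind(out, cur)
  rownames(out) <- NULL
  out
}

#' Compute minimum and maximum event spans
#'
#' The minimum span runs from the 3' end of the first supporting bin to the
#' 5' end of the last supporting bin (an inner bound on the event); the
#' maximum span runs from the 5' end of the nearest informative
#' non-supporting bin on the left to the 3' end of the nearest informative
#' non-supporting bin on the right (an outer bound).  Chromosome edges (0 and
#' the chromosome length) substitute where no flanking informative bin
#' exists.  A call supported by a single bin has an empty minimum span; its
#' width is reported as 0 and flagged `degenerate_span`.  The exported single
#' event size (`size_kbp`) is the minimum-span length for all three CNV
#' types.
#'
#' @param calls Candidate-call data.frame (bin indices are positions in the
#'   chromosome's informative-bin sequence).
#' @param r The `ratio_matrix` the calls came from.
#' @return `calls` with added columns `min_start`, `min_end`, `max_start`,
#'   `max_end` (0-based half-open bp), `size_kbp`, `degenerate_span`.
#' @export
compute_spans <- function(calls, r) {
  stopifnot(inherits(r, "ratio_matrix"))
  n <- nrow(calls)
  cols <- c("min_start", "min_end", "max_start", "max_end")
  for (cc in cols) calls[[cc]] <- numeric(n)
  calls$size_kbp <- numeric(n)
  calls$degenerate_span <- logical(n)
  if (n == 0) return(calls)
  chr_len <- stats::setNames(r$grid$chromosomes$length,
                             r$grid$chromosomes$name)
  for (ch in unique(calls$chrom)) {
    bins <- r$bins[r$bins$chrom == ch, , drop = FALSE]
    rows <- which(calls$chrom == ch)
    for (i in rows) {
      fb <- calls$first_bin[i]; lb <- calls$last_bin[i]
      min_start <- bins$end[fb]
      min_end <- bins$start[lb]
      if (min_end <= min_start) {          # 1 bin, or adjacent bins
        calls$degenerate_span[i] <- TRUE
        min_end <- min_start
      }
      calls$min_start[i] <- min_start
      calls$min_end[i] <- min_end
      calls$max_start[i] <- if (fb > 1) bins$start[fb - 1] else 0
      calls$max_end[i] <- if (lb < nrow(bins)) bins$end[lb + 1] else
        unname(chr_len[ch])
      calls$size_kbp[i] <- (min_end - min_start) / 1000
    }
  }
  calls
}

#' Drop calls overlapping exclusion regions
#'
#' Removes any call whose maximum span overlaps an exclusion interval by at
#' least 1 bp.  Exclusion regions typically mark naturally occurring
#' heterogeneity in the population's genetic background, where apparent CNVs
#' are not mutagen-induced.
#'
#' @param calls Call data.frame with span columns (see [compute_spans()]).
#' @param exclusions A data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), a `GRanges`, or `NULL`/empty for no-op.
#' @param verbose Log removed calls with `message()`.
#' @export
exclude_regions <- function(calls, exclusions, verbose = FALSE) {
  if (is.null(exclusions) || nrow(calls) == 0) return(calls)
  if (!inherits(exclusions, "GRanges")) {
    if (nrow(exclusions) == 0) return(calls)
    if (any(exclusions$start >= exclusions$end))
      stop("exclusion intervals must have start < end")
    exclusions <- GenomicRanges::GRanges(
      exclusions$chrom,
      IRanges::IRanges(exclusions$start + 1, exclusions$end))
  } else if (length(exclusions) == 0) return(calls)
  spans <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$max_start + 1, calls$max_end))
  hit <- IRanges::overlapsAny(spans, exclusions)
  if (verbose && any(hit))
    message("exclude_regions: removing ", sum(hit), " call(s): ",
            paste(calls$sample[hit], calls$type[hit], calls$chrom[hit],
                  sep = ":", collapse = ", "))
  calls[!hit, , drop = FALSE]
}

#' Bundled pipeline parameters
#'
#' All tunables of the GBS CNV pipeline in one object.  The `"strict"`
#' preset is the default calling configuration (bin filters 150 / 7 / 3,
#' min-mean 8 for the hemizygous-deletion dataset; class boundaries
#' -2.5 / -0.5 / 0.2; support minima 3 and 6 bins).  The `"relaxed"` preset
#' lowers the support minima to 1 and 2 bins, trading precision for
#' sensitivity when known CNVs are being tracked rather than discovered.
#'
#' In the relaxed preset the segmentation penalty is also lowered (to
#' `penalty_beta` below `loss_cutoff_K^2`), so that even a single saturated
#' bin can open a segment -- the behaviour a one-to-two-bin support minimum
#' requires.
#'
#' @param preset `"strict"` or `"relaxed"`.
#' @param filter_homdel_dup,filter_hetdel [filter_params()] per dataset.
#' @param seg_homdel_dup,seg_hetdel [seg_params()] per dataset (`NULL` =
#'   preset default).
#' @param thresholds A [class_thresholds()] (`NULL` = preset default).
#' @return An object of class `pipeline_params`.
#' @export
pipeline_params <- function(preset = c("strict", "relaxed"),
                            filter_homdel_dup = filter_params(min_mean = 7),
                            filter_hetdel = filter_params(min_mean = 8),
                            seg_homdel_dup = NULL,
                            seg_hetdel = NULL,
                            thresholds = NULL) {
  preset <- match.arg(preset)
  default_seg <- if (preset == "relaxed")
    seg_params(penalty_beta = 6) else seg_params()
  if (is.null(seg_homdel_dup)) seg_homdel_dup <- default_seg
  if (is.null(seg_hetdel)) seg_hetdel <- default_seg
  if (is.null(thresholds)) {
    thresholds <- if (preset == "relaxed")
      class_thresholds(min_bins_homdel = 1, min_bins_hetdup = 2)
    else class_thresholds()
  }
  structure(list(preset = preset, filter_homdel_dup = filter_homdel_dup,
                 filter_hetdel = filter_hetdel,
                 seg_homdel_dup = seg_homdel_dup, seg_hetdel = seg_hetdel,
                 thresholds = thresholds),
            class = "pipeline_params")
}

# One dataset through the full chain:
# normalize -> filter -> ratio -> segment -> classify -> support -> merge ->
# spans -> exclusion.  Spans precede exclusion because the overlap rule is
# defined on the maximum span.
.call_dataset <- function(m, fp, sp, thresholds, keep_types, dataset,
                          exclusions, verbose = FALSE) {
  norm <- normalize_counts(m)
  fr <- filter_bins(norm, fp)
  r <- log2_ratio(norm, fr$mask)
  segs <- segment_all(r, sp)
  calls <- classify_segments(segs, thresholds, dataset = dataset)
  calls <- calls[calls$type %in% keep_types, , drop = FALSE]
  calls <- filter_support(calls, thresholds)
  calls <- merge_contiguous(calls)
  calls <- compute_spans(calls, r)
  calls <- exclude_regions(calls, exclusions, verbose = verbose)
  list(calls = calls, report = fr$report, ratio = r)
}

#' Call CNVs from GBS count matrices
#'
#' Full pipeline over the two mapping-quality datasets: homozygous deletions
#' and duplications are called from the MQ >= 20 tally, hemizygous deletions
#' from the MQ >= 35 tally (higher stringency suppresses the paralog noise
#' that mimics intermediate log2 ratios).  Per dataset the chain is
#' normalize, filter bins, log2 ratios, segment, classify, support filter,
#' merge contiguous calls, compute spans, apply exclusion regions.
#'
#' @param mq20_matrix,mq35_matrix Raw `count_matrix` objects on the same
#'   grid and sample set.  Pass the same object twice when only one tally is
#'   available.
#' @param params A [pipeline_params()].
#' @param exclusions Exclusion regions (see [exclude_regions()]) or `NULL`.
#' @param excluded_samples Sample IDs dropped before normalization
#'   (e.g. lines failing a contamination screen).
#' @param verbose Log exclusions.
#' @return An object of class `cnv_calls`: a data.frame of calls (one row
#'   per event) with attributes `filter_reports` (per dataset) and `ratios`
#'   (per-dataset `ratio_matrix`, for profile plots).
#' @export
call_cnvs <- function(mq20_matrix, mq35_matrix = mq20_matrix,
                      params = pipeline_params(), exclusions = NULL,
                      excluded_samples = character(), verbose = FALSE) {
  stopifnot(inherits(mq20_matrix, "count_matrix"),
            inherits(mq35_matrix, "count_matrix"),
            inherits(params, "pipeline_params"))
  if (!identical(mq20_matrix$grid$bins, mq35_matrix$grid$bins))
    stop("the two datasets must share one bin grid")
  if (!setequal(mq20_matrix$samples, mq35_matrix$samples))
    stop("the two datasets must share one sample set")
  drop_samples <- function(m) {
    keep <- !(m$samples %in% excluded_samples)
    count_matrix(m$counts[keep, , drop = FALSE], m$grid, m$samples[keep],
                 library_id = m$library_id, tally = m$tally)
  }
  m20 <- drop_samples(mq20_matrix)
  m35 <- drop_samples(mq35_matrix)
  hd <- .call_dataset(m20, params$filter_homdel_dup, params$seg_homdel_dup,
                      params$thresholds, c("homdel", "dup"), "mq20",
                      exclusions, verbose)
  hz <- .call_dataset(m35, params$filter_hetdel, params$seg_hetdel,
                      params$thresholds, "hetdel", "mq35",
                      exclusions, verbose)
  calls <- rbind(hd$calls, hz$calls)
  o <- order(calls$sample, calls$chrom, calls$min_start)
  calls <- calls[o, , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, class = c("cnv_calls", "data.frame"),
            filter_reports = list(mq20 = hd$report, mq35 = hz$report),
            ratios = list(mq20 = hd$ratio, mq35 = hz$ratio))
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat("cnv_calls:", nrow(x), "event(s) in",
      length(unique(x$sample)), "sample(s)\n")
  if (nrow(x) > 0) {
    tb <- table(factor(x$type, levels = c("homdel", "hetdel", "dup")))
    cat("  homozygous deletions:", tb[["homdel"]],
        " hemizygous deletions:", tb[["hetdel"]],
        " duplications:", tb[["dup"]], "\n")
    print.data.frame(x[, c("sample", "type", "chrom", "min_start", "min_end",
                           "size_kbp", "n_bins", "mean_log2")],
                     row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.cnv_calls <- function(object, ...) {
  if (nrow(object) == 0) { cat("no CNV calls\n"); return(invisible(NULL)) }
  by_type <- split(object$size_kbp, object$type)
  cat("CNV calls by type (size = minimum span, kbp):\n")
  for (ty in names(by_type))
    cat(sprintf("  %-7s n=%3d  median %.1f  range [%.1f, %.1f]\n", ty,
                length(by_type[[ty]]), median(by_type[[ty]]),
                min(by_type[[ty]]), max(by_type[[ty]])))
  invisible(by_type)
}

#' @export
plot.cnv_calls <- function(x, ...) {
  if (nrow(x) == 0) stop("no calls to plot")
  types <- factor(x$type, levels = c("homdel", "hetdel", "dup"))
  sz <- pmax(x$size_kbp, 0.1)
  graphics::stripchart(sz ~ types, vertical = TRUE, method = "jitter",
                       pch = 19, log = "y", ylab = "minimum span (kbp)",
                       xlab = "", ...)
  invisible(x)
}

#' Flag suspicious samples
#'
#' Reports (never removes) samples whose raw read total falls below a
#' fraction of the population median and samples whose call count exceeds a
#' Tukey-style outlier bound, both symptoms that their calls may be spurious.
#'
#' @param calls A `cnv_calls` table (or any data.frame with a `sample`
#'   column).
#' @param m The raw `count_matrix` the calls derive from.
#' @param depth_fraction Samples below `depth_fraction * median(total)` are
#'   flagged (default 0.5).
#' @param iqr_multiplier Samples with more than `Q3 + iqr_multiplier * IQR`
#'   calls are flagged (default 3).
#' @return A data.frame with one row per sample: `sample`, `total_reads`,
#'   `n_calls`, `low_depth`, `excess_calls`.
#' @export
sample_qc <- function(calls, m, depth_fraction = 0.5, iqr_multiplier = 3) {
  stopifnot(inherits(m, "count_matrix"))
  totals <- rowSums(m$counts)
  n_calls <- vapply(m$samples,
                    function(s) sum(calls$sample == s), 0L)
  q <- quantile(n_calls, c(0.25, 0.75))
  bound <- q[2] + iqr_multiplier * (q[2] - q[1])
  data.frame(sample = m$samples, total_reads = unname(totals),
             n_calls = unname(n_calls),
             low_depth = unname(totals < depth_fraction * median(totals)),
             excess_calls = unname(n_calls > bound),
             stringsAsFactors = FALSE)
}
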