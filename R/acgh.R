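#' aCGH homozygous-deletion calling parameters
#'
#' A probe segment is labeled a homozygous deletion when its mean log2 ratio
#' is strictly below `homdel_max` (default -3, i.e. a hybridization ratio of
#' 1/8); labeled segments are merged when contiguous and discarded when
#' supported by fewer than `min_probes` probes.  Hemizygous deletions and
#' duplications are deliberately not auto-called from aCGH: their milder
#' log2 shifts resist a single parameterization, so they enter the
#' validation workflow as externally curated truth records (see
#' [load_truth_table()]).  An opt-in thresholding mode for them exists via
#' `call_het_dup = TRUE` but is excluded from validation defaults.
#'
#' @param homdel_max Log2-ratio ceiling for a homozygous deletion
#'   (exclusive).
#' @param min_probes Minimum supporting probes.
#' @param seg A [seg_params()] for the probe-profile segmentation.
#' @return An object of class `acgh_params`.
#' @export
acgh_params <- function(homdel_max = -3, min_probes = 3,
                        seg = seg_params()) {
  if (min_probes < 1) stop("min_probes must be >= 1")
  structure(list(homdel_max = homdel_max, min_probes = min_probes,
                 seg = seg), class = "acgh_params")
}

#' Call homozygous deletions from an aCGH probe profile
#'
#' Segments each chromosome's ordered probe log2 ratios with the same
#' penalized robust changepoint engine used for GBS profiles, labels
#' segments with mean below the threshold as deletions, merges contiguous
#' labeled segments, discards calls with too few probes, removes calls
#' overlapping exclusion regions, and reports the span from the 3' end of
#' the first supporting probe to the 5' end of the last supporting probe.
#' Note that merging precedes the probe-count filter, so two small adjacent
#' labeled segments can jointly survive the filter.
#'
#' @param profile A data.frame with columns `sample`, `chrom`, `start`,
#'   `end` (probe coordinates, 0-based half-open), `log2_ratio`, sorted by
#'   (chrom, start) within sample.  Multiple samples are processed
#'   independently.
#' @param params An [acgh_params()].
#' @param exclusions Exclusion regions (see [exclude_regions()]) or `NULL`.
#' @param call_het_dup Also threshold hemizygous deletions and duplications
#'   using [class_thresholds()] boundaries (off by default; see
#'   [acgh_params()]).
#' @param thresholds Used only when `call_het_dup = TRUE`.
#' @return A data.frame of calls: `sample`, `type`, `chrom`, `start`, `end`
#'   (0-based half-open span), `kbp`, `n_probes`, `mean_log2`.
#' @export
call_acgh_homdels <- function(profile, params = acgh_params(),
                              exclusions = NULL, call_het_dup = FALSE,
                              thresholds = class_thresholds()) {
  need <- c("sample", "chrom", "start", "end", "log2_ratio")
  if (!all(need %in% names(profile)))
    stop("profile needs columns ", paste(need, collapse = ", "))
  if (any(!is.finite(profile$log2_ratio)))
    stop("probe log2 ratios must be finite")
  out <- list()
  for (s in unique(profile$sample)) {
    ps <- profile[profile$sample == s, , drop = FALSE]
    for (ch in unique(ps$chrom)) {
      pc <- ps[ps$chrom == ch, , drop = FALSE]
      if (is.unsorted(pc$start)) stop("probes must be sorted by position")
      sg <- .segment_maybe_std(pc$log2_ratio, params$seg)
      lab <- sg$segment_means < params$homdel_max
      type <- ifelse(lab, "homdel", NA_character_)
      if (call_het_dup) {
        alt <- .classify_mean(sg$segment_means, thresholds)
        type[!lab & !is.na(alt) & alt != "homdel"] <- alt[!lab &
          !is.na(alt) & alt != "homdel"]
      }
      keep <- which(!is.na(type))
      if (length(keep) == 0) next
      calls <- data.frame(sample = s, type = type[keep], chrom = ch,
                          first_bin = sg$starts[keep],
                          last_bin = sg$ends[keep],
                          n_bins = sg$ends[keep] - sg$starts[keep] + 1L,
                          mean_log2 = sg$segment_means[keep],
                          dataset = "acgh", stringsAsFactors = FALSE)
      calls <- merge_contiguous(calls)
      calls <- calls[calls$n_bins >= params$min_probes, , drop = FALSE]
      if (nrow(calls) == 0) next
      # span: 3' end of first supporting probe to 5' start of last
      calls$start <- pc$end[calls$first_bin]
      calls$end <- pc$start[calls$last_bin]
      calls$end <- pmax(calls$end, calls$start)
      # outer bound for exclusion overlap: flanking probes or profile edge
      calls$max_start <- ifelse(calls$first_bin > 1,
                                pc$start[pmax(calls$first_bin - 1, 1)], 0)
      calls$max_end <- ifelse(calls$last_bin < nrow(pc),
                              pc$end[pmin(calls$last_bin + 1, nrow(pc))],
                              max(pc$end))
      calls <- exclude_regions(calls, exclusions)
      if (nrow(calls) == 0) next
      out[[length(out) + 1]] <- data.frame(
        sample = calls$sample, type = calls$type, chrom = calls$chrom,
        start = calls$start, end = calls$end,
        kbp = (calls$end - calls$start) / 1000,
        n_probes = calls$n_bins, mean_log2 = calls$mean_log2,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(), type = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), kbp = numeric(),
                      n_probes = integer(), mean_log2 = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Load an externally curated CNV truth table
#'
#' Reads a CSV of validated CNV events (schema: `ID`, `CNV_type`, `chr`,
#' `start`, `end`, `kbp`, plus any extra columns such as `n_probes`,
#' `mean_log2` or `found_by_GBS`).  Coordinates on disk are 1-based
#' inclusive and are converted to the package's 0-based half-open frame.
#' Hemizygous-deletion and duplication rows are accepted as visually or
#' externally called truth records.
#'
#' @param path CSV file path.
#' @return A data.frame with at least `sample`, `type`, `chrom`, `start`,
#'   `end`, `kbp`.
#' @export
load_truth_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("ID", "CNV_type", "chr", "start", "end")
  if (!all(need %in% names(df)))
    stop("truth table must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$CNV_type), c("homdel", "hetdel", "dup"))
  if (length(bad) > 0)
    stop("unknown CNV_type token(s): ", paste(bad, collapse = ", "))
  if (any(df$end < df$start))
    stop("truth rows with end < start: ",
         paste(which(df$end < df$start), collapse = ", "))
  out <- data.frame(sample = df$ID, type = df$CNV_type, chrom = df$chr,
                    start = df$start - 1, end = df$end,
                    kbp = if ("kbp" %in% names(df)) df$kbp else
                      (df$end - df$start + 1) / 1000,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c(need, "kbp"))
  for (cc in extra) out[[cc]] <- df[[cc]]
  out
}
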