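#' Normalize read counts across samples
#'
#' Rescales each sample's counts by a per-sample factor so that every sample
#' ends up with the same total read count.  The common target is the mean of
#' the original per-sample totals, which preserves the grand total of reads
#' and leaves within-sample proportions untouched.
#'
#' @param m A raw `count_matrix`.
#' @return A real-valued, normalized `count_matrix`.
#' @export
normalize_counts <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  totals <- rowSums(m$counts)
  if (any(totals == 0))
    stop("sample(s) with zero total reads: ",
         paste(m$samples[totals == 0], collapse = ", "))
  target <- mean(totals)
  out <- m$counts * (target / totals)
  count_matrix(out, m$grid, m$samples, library_id = m$library_id,
               tally = m$tally, normalized = TRUE)
}

#' Bin-filtering parameters
#'
#' The three sequential filters that reduce the bin set to informative bins:
#' bins with a mean normalized count per sample above `max_mean` are dropped
#' (suspected paralogous or organellar-homology pile-ups), bins with mean
#' below `min_mean` are dropped (insufficient power), and bins whose
#' across-sample variance-to-mean ratio exceeds `varmean_max` are dropped
#' (erratic bins prone to spurious calls).  Defaults are 150 / 7 / 3 for the
#' dataset used to call homozygous deletions and duplications; `min_mean` is
#' 8 for the hemizygous-deletion dataset (see [pipeline_params()]).
#'
#' @param max_mean,min_mean,varmean_max Filter thresholds.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(max_mean = 150, min_mean = 7, varmean_max = 3) {
  if (!(max_mean > min_mean && min_mean > 0)) stop("need max_mean > min_mean > 0")
  if (varmean_max <= 0) stop("varmean_max must be positive")
  structure(list(max_mean = max_mean, min_mean = min_mean,
                 varmean_max = varmean_max), class = "filter_params")
}

#' Select informative bins
#'
#' Applies the three filters of [filter_params()] sequentially (max-mean,
#' then min-mean, then variance/mean) on a normalized count matrix.  Bins
#' with zero reads in every sample are set aside before step accounting, so
#' the report starts from bins with at least one read.  Each removed bin is
#' attributed to the first filter that rejects it.  Variance is the sample
#' variance (n - 1 denominator).
#'
#' @param m A normalized `count_matrix`.
#' @param p A [filter_params()].
#' @return A list of class `filter_result` with `mask` (logical over grid
#'   bins, `TRUE` = informative) and `report` (class `filter_report`):
#'   `n_bins_nonzero`, `removed_max`, `removed_min`, `removed_varmean`,
#'   `n_informative`, `n_reads_initial`, `n_reads_informative`.
#' @export
filter_bins <- function(m, p = filter_params()) {
  stopifnot(inherits(m, "count_matrix"), inherits(p, "filter_params"))
  if (!m$normalized)
    warning("filter_bins expects normalized counts; filtering raw counts")
  cnt <- m$counts
  means <- colMeans(cnt)
  nonzero <- colSums(cnt) > 0
  vars <- apply(cnt, 2, var)
  vm <- ifelse(means > 0, vars / means, 0)

  state <- ifelse(nonzero, "kept", "zero")
  state[state == "kept" & means > p$max_mean] <- "max"
  state[state == "kept" & means < p$min_mean] <- "min"
  state[state == "kept" & vm > p$varmean_max] <- "varmean"

  mask <- state == "kept"
  report <- structure(list(
    n_bins_nonzero = sum(nonzero),
    removed_max = sum(state == "max"),
    removed_min = sum(state == "min"),
    removed_varmean = sum(state == "varmean"),
    n_informative = sum(mask),
    n_reads_initial = sum(cnt),
    n_reads_informative = sum(cnt[, mask, drop = FALSE])),
    class = "filter_report")
  if (report$n_informative == 0) warning("no informative bins remain")
  structure(list(mask = mask, report = report), class = "filter_result")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Bins with at least 1 read:  ", x$n_bins_nonzero, "\n",
      "Removed by max-read filter: ", x$removed_max, "\n",
      "Removed by min-read filter: ", x$removed_min, "\n",
      "Removed by var/mean filter: ", x$removed_varmean, "\n",
      "Informative bins remaining: ", x$n_informative, "\n",
      "Reads initial/in informative bins: ", round(x$n_reads_initial), " / ",
      round(x$n_reads_informative), "\n", sep = "")
  invisible(x)
}

#' Write a bin-filter report as TSV
#' @param x A `filter_report`.
#' @param path Output file.
#' @export
write_filter_report <- function(x, path) {
  df <- data.frame(step = names(unclass(x)),
                   value = as.numeric(unlist(unclass(x))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-bin log2 ratios against the population mean
#'
#' For each sample i and informative bin j, computes
#' `r_ij = log2((n_ij + 1) / (m_j + 1))` where `n_ij` is the normalized
#' count and `m_j` the mean normalized count over all samples (including the
#' focal one) in bin j.  The +1 pseudo-counts keep the ratios finite at zero
#' coverage; with a population-mean depth around 7 reads, a homozygous
#' deletion therefore sits near `log2(1/8) = -3`.
#'
#' @param m A normalized `count_matrix`.
#' @param mask Logical mask of informative bins (from [filter_bins()]), a
#'   `filter_result`, or `NULL` to use every bin.
#' @return An object of class `ratio_matrix`: list with `samples`, `bins`
#'   (data.frame `chrom`, `start`, `end`, `grid_index`), `ratios`
#'   (samples x informative bins), `bin_means` (m_j), and `grid`.
#' @export
log2_ratio <- function(m, mask = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (inherits(mask, "filter_result")) mask <- mask$mask
  if (is.null(mask)) mask <- rep(TRUE, ncol(m$counts))
  cnt <- m$counts[, mask, drop = FALSE]
  m_j <- colMeans(cnt)
  ratios <- log2(sweep(cnt + 1, 2, m_j + 1, "/"))
  bins <- m$grid$bins[mask, , drop = FALSE]
  bins$grid_index <- which(mask)
  rownames(bins) <- NULL
  structure(list(samples = m$samples, bins = bins, ratios = ratios,
                 bin_means = m_j, grid = m$grid),
            class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat("ratio_matrix:", length(x$samples), "samples x", nrow(x$bins),
      "informative bins\n")
  invisible(x)
}

#' Write a ratio matrix as TSV (chrom, start, end, one column per sample)
#' @param r A `ratio_matrix`.
#' @param path Output file.
#' @export
write_ratio_matrix <- function(r, path) {
  df <- data.frame(chrom = r$bins$chrom, start = r$bins$start + 1L,
                   end = r$bins$end, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(t(r$ratios)))
  names(df) <- c("chrom", "start", "end", r$samples)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
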