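#' Construct a per-bin read count matrix
#'
#' Container for samples x bins read counts on a [make_bin_grid()] frame.
#' Counts are integers straight from tallying and become reals after
#' [normalize_counts()].
#'
#' @param counts Numeric matrix, samples in rows, bins in columns (column
#'   count must equal `length(grid)`).
#' @param grid A `bin_grid`.
#' @param samples Sample identifiers; defaults to `rownames(counts)`.
#' @param library_id Label of the sequencing library the counts came from.
#' @param tally The [tally_config()] used, if known.
#' @param normalized Logical; have counts been depth-normalized?
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, grid, samples = rownames(counts),
                         library_id = "lib", tally = NULL,
                         normalized = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(samples)) stop("sample names are required")
  if (!inherits(grid, "bin_grid")) stop("grid must be a bin_grid")
  if (ncol(counts) != length(grid))
    stop("counts has ", ncol(counts), " columns but grid has ",
         length(grid), " bins")
  if (nrow(counts) != length(samples))
    stop("counts has ", nrow(counts), " rows but ", length(samples),
         " sample names were given")
  if (anyDuplicated(samples)) stop("duplicate sample names")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  rownames(counts) <- samples
  structure(list(samples = as.character(samples), grid = grid,
                 counts = counts, library_id = library_id, tally = tally,
                 normalized = normalized),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", length(x$samples), " samples x ", ncol(x$counts),
      " bins (library ", x$library_id, ", ",
      if (x$normalized) "normalized" else "raw", ")\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Sum the raw counts of two libraries
#'
#' Element-wise sum of two count matrices over the same bin grid and sample
#' set, used to pool sequencing libraries (e.g. two size-selection protocols)
#' before normalization.  Samples are aligned by ID, so row order may differ.
#'
#' @param a,b `count_matrix` objects with identical grids and sample sets.
#' @return A `count_matrix` of summed raw counts; `library_id` records both
#'   sources.
#' @export
combine_libraries <- function(a, b) {
  stopifnot(inherits(a, "count_matrix"), inherits(b, "count_matrix"))
  if (a$normalized || b$normalized)
    stop("combine_libraries operates on raw counts")
  if (!identical(a$grid$bins, b$grid$bins))
    stop("bin grids differ between libraries")
  if (!setequal(a$samples, b$samples)) {
    d <- c(setdiff(a$samples, b$samples), setdiff(b$samples, a$samples))
    stop("sample sets differ; not shared: ", paste(d, collapse = ", "))
  }
  bb <- b$counts[a$samples, , drop = FALSE]
  count_matrix(a$counts + bb, a$grid, a$samples,
               library_id = paste(a$library_id, b$library_id, sep = "+"),
               tally = a$tally)
}

#' Read / write count matrices as TSV
#'
#' Plain-text interchange format: columns `chrom`, `start`, `end` (1-based
#' inclusive on disk), then one column per sample.  Gzip-compressed files are
#' read and written transparently from their `.gz` suffix.
#'
#' @param path File path.
#' @param grid Optional `bin_grid`; if omitted, a grid is reconstructed from
#'   the coordinate columns (chromosome length taken as the last bin end).
#' @param library_id,tally Passed to [count_matrix()].
#' @param sep Field separator (default tab).
#' @return `load_count_matrix()` returns a `count_matrix`;
#'   `write_count_matrix()` returns `path` invisibly.
#' @export
load_count_matrix <- function(path, grid = NULL, library_id = "lib",
                              tally = NULL, sep = "\t") {
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("count matrix file must have columns chrom, start, end")
  sample_cols <- setdiff(names(df), need)
  if (length(sample_cols) == 0) stop("no sample columns found")
  for (cc in sample_cols)
    if (!is.numeric(df[[cc]]))
      stop("non-numeric counts in column '", cc, "' (first bad row: ",
           which(!grepl("^-?[0-9.eE+-]+$", as.character(df[[cc]])))[1], ")")
  if (is.null(grid)) {
    lens <- tapply(df$end, df$chrom, max)
    sizes <- df$end - df$start + 1
    grid <- make_bin_grid(lens[unique(df$chrom)],
                          bin_size = max(sizes))
  }
  if (nrow(df) != length(grid))
    stop("file has ", nrow(df), " bins but grid has ", length(grid))
  counts <- t(as.matrix(df[, sample_cols, drop = FALSE]))
  if (any(counts < 0)) stop("negative counts in file")
  count_matrix(counts, grid, sample_cols, library_id = library_id,
               tally = tally)
}

#' @rdname load_count_matrix
#' @param m A `count_matrix`.
#' @export
write_count_matrix <- function(m, path, sep = "\t") {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(chrom = m$grid$bins$chrom,
                   start = m$grid$bins$start + 1L,  # 1-based inclusive on disk
                   end = m$grid$bins$end,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(t(m$counts)))
  names(df) <- c("chrom", "start", "end", m$samples)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
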