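#' Build a fixed-width bin grid over nuclear chromosomes
#'
#' Tiles each chromosome with consecutive bins of `bin_size` base pairs, the
#' coordinate frame into which GBS reads are counted.  Coordinates are 0-based
#' half-open internally; the last bin of a chromosome may be shorter than
#' `bin_size`.  Organellar and scaffold sequences must be omitted by the
#' caller: they exist in the alignment reference only to absorb reads and are
#' not part of the CNV coordinate frame.
#'
#' @param chromosomes Named integer/numeric vector of chromosome lengths in
#'   bp, or a data.frame with columns `name` and `length`.
#' @param bin_size Bin width in bp (default 1000, i.e. 1-kb bins).
#' @return An object of class `bin_grid`: a list with `chromosomes`
#'   (data.frame `name`, `length`), `bin_size`, and `bins` (data.frame
#'   `chrom`, `start`, `end`, 0-based half-open, in chromosome order).
#' @examples
#' make_bin_grid(c(chr1 = 2500), bin_size = 1000)
#' @export
make_bin_grid <- function(chromosomes, bin_size = 1000) {
  if (is.data.frame(chromosomes)) {
    chrom <- data.frame(name = as.character(chromosomes$name),
                        length = as.numeric(chromosomes$length),
                        stringsAsFactors = FALSE)
  } else {
    if (is.null(names(chromosomes)) || any(names(chromosomes) == ""))
      stop("chromosome lengths must be named")
    chrom <- data.frame(name = names(chromosomes),
                        length = as.numeric(chromosomes),
                        stringsAsFactors = FALSE)
  }
  if (anyDuplicated(chrom$name))
    stop("duplicate chromosome name: ",
         paste(unique(chrom$name[duplicated(chrom$name)]), collapse = ", "))
  if (any(!is.finite(chrom$length)) || any(chrom$length <= 0))
    stop("chromosome lengths must be positive")
  if (!is.finite(bin_size) || bin_size <= 0) stop("bin_size must be positive")

  bins <- do.call(rbind, lapply(seq_len(nrow(chrom)), function(i) {
    len <- chrom$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = chrom$name[i], start = starts,
               end = pmin(starts + bin_size, len), stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  structure(list(chromosomes = chrom, bin_size = bin_size, bins = bins),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("bin_grid:", nrow(x$chromosomes), "chromosomes,", nrow(x$bins),
      "bins of", x$bin_size, "bp\n")
  invisible(x)
}

#' @export
length.bin_grid <- function(x) nrow(x$bins)

# 1-based row indices into grid$bins for 0-based positions on a chromosome;
# NA for positions outside the chromosome or chromosomes absent from the grid
bin_index <- function(grid, chrom, pos) {
  chrom_rows <- split(seq_len(nrow(grid$bins)), grid$bins$chrom)
  lens <- stats::setNames(grid$chromosomes$length, grid$chromosomes$name)
  offset <- vapply(chrom_rows, min, 0L) - 1L
  idx <- rep(NA_integer_, length(pos))
  known <- chrom %in% names(chrom_rows)
  inside <- known
  inside[known] <- pos[known] >= 0 & pos[known] < lens[chrom[known]]
  idx[inside] <- offset[chrom[inside]] +
    as.integer(pos[inside] %/% grid$bin_size) + 1L
  idx
}
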