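#' Read genomic intervals from a BED file
#'
#' @param path BED file (0-based half-open).
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `name` when present.
#' @export
read_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1,
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
    if (!is.null(gr$name)) df$name <- gr$name
    return(df)
  }
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  out <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- df[[4]]
  out
}

#' Read gene models from GFF3 or BED
#'
#' Extracts `gene`-type features from a GFF3 file (or all intervals from a
#' BED file) as the gene table consumed by [count_affected_genes()].
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED file.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `id`.
#' @export
read_genes <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    df <- read_bed(path)
    df$id <- if (!is.null(df$name)) df$name else
      paste0("gene", seq_len(nrow(df)))
    return(df[, c("chrom", "start", "end", "id")])
  }
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "GFF3")
    gr <- gr[gr$type == "gene"]
    id <- if (!is.null(gr$ID)) gr$ID else paste0("gene", seq_along(gr))
    return(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1,
                      end = GenomicRanges::end(gr), id = id,
                      stringsAsFactors = FALSE))
  }
  df <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  df <- df[df[[3]] == "gene", , drop = FALSE]
  data.frame(chrom = df[[1]], start = df[[4]] - 1, end = df[[5]],
             id = sub('.*ID=([^;]+).*', '\\1', df[[9]]),
             stringsAsFactors = FALSE)
}

#' Export CNV calls as CSV
#'
#' Writes the exchange schema `ID`, `CNV_type`, `chr`, `start`, `end`,
#' `kbp`, `n_bins`, `mean_log2` with 1-based inclusive minimum-span
#' coordinates, readable back through [load_truth_table()].
#'
#' @param calls A `cnv_calls` table (or compatible data.frame).
#' @param path Output CSV.
#' @export
write_cnv_csv <- function(calls, path) {
  df <- data.frame(ID = calls$sample, CNV_type = calls$type,
                   chr = calls$chrom, start = calls$min_start + 1,
                   end = calls$min_end, kbp = calls$size_kbp,
                   n_bins = calls$n_bins,
                   mean_log2 = round(calls$mean_log2, 4),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export CNV calls as BED6
#'
#' Minimum-span intervals (0-based half-open), `name` = `sample:type`,
#' `score` = `round(-10 * mean_log2)` clamped to [0, 1000].
#'
#' @param calls A `cnv_calls` table.
#' @param path Output BED.
#' @export
write_cnv_bed <- function(calls, path) {
  score <- pmin(pmax(round(-10 * calls$mean_log2), 0), 1000)
  df <- data.frame(chrom = calls$chrom, start = calls$min_start,
                   end = pmax(calls$min_end, calls$min_start + 1),
                   name = paste(calls$sample, calls$type, sep = ":"),
                   score = score, strand = ".", stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
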