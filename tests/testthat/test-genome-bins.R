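test_that("bin grids tile chromosomes without gaps or overlaps", {
  g <- make_bin_grid(c(chr1 = 2500), bin_size = 1000)
  expect_equal(g$bins$start, c(0, 1000, 2000))
  expect_equal(g$bins$end, c(1000, 2000, 2500))

  g1 <- make_bin_grid(c(chr1 = 1000))
  expect_equal(nrow(g1$bins), 1)
  expect_equal(g1$bins$end, 1000)

  g2 <- make_bin_grid(c(a = 1500, b = 999))
  expect_equal(nrow(g2$bins), 3)
  expect_equal(g2$bins$chrom, c("a", "a", "b"))
  # tiling invariant on a generated grid
  g3 <- make_bin_grid(c(x = 12345, y = 7000), bin_size = 1000)
  for (ch in c("x", "y")) {
    b <- g3$bins[g3$bins$chrom == ch, ]
    expect_equal(b$start[-1], b$end[-nrow(b)])   # no gaps, no overlaps
    expect_true(all(b$end - b$start <= 1000 & b$end - b$start >= 1))
  }

  expect_error(make_bin_grid(c(a = 100, a = 200)), "duplicate")
  expect_error(make_bin_grid(c(a = -5)), "positive")
})

test_that("read tallying follows the 5' and distal conventions", {
  grid <- make_bin_grid(c(chr1 = 5000))
  # plus-strand read, 5' (leftmost) at 0-based 999, aligned span 150
  plus <- data.frame(chrom = "chr1", pos = 999, width = 150, strand = "+",
                     mapq = 60, stringsAsFactors = FALSE)
  m5 <- tally_reads(plus, grid, tally_config(mode = "five_prime_both"))
  expect_equal(which(m5$counts[1, ] > 0), 1L)        # bin [0,1000)
  md <- tally_reads(plus, grid, tally_config(mode = "distal"))
  expect_equal(which(md$counts[1, ] > 0), 2L)        # 3' end 1148
  # minus-strand read whose 5' (rightmost) coordinate is 1148
  minus <- data.frame(chrom = "chr1", pos = 999, width = 150, strand = "-",
                      mapq = 60, stringsAsFactors = FALSE)
  for (mode in c("five_prime_both", "distal")) {
    mm <- tally_reads(minus, grid, tally_config(mode = mode))
    expect_equal(which(mm$counts[1, ] > 0), 2L)
  }
})

test_that("mapping-quality and contig filters drop the right reads", {
  grid <- make_bin_grid(c(chr1 = 5000))
  reads <- data.frame(chrom = c("chr1", "chr1", "scaffold_1"),
                      pos = c(100, 200, 300), width = 100,
                      strand = "+", mapq = c(34, 40, 60),
                      stringsAsFactors = FALSE)
  m20 <- tally_reads(reads, grid, tally_config(mq_min = 20))
  expect_equal(sum(m20$counts), 2)    # MAPQ 34 counted, scaffold ignored
  m35 <- tally_reads(reads, grid, tally_config(mq_min = 35))
  expect_equal(sum(m35$counts), 1)    # MAPQ 34 excluded
  # out-of-range coordinate warns and is skipped
  bad <- data.frame(chrom = "chr1", pos = 6000, width = 100, strand = "+",
                    mapq = 60, stringsAsFactors = FALSE)
  expect_warning(mb <- tally_reads(bad, grid, tally_config()), "outside")
  expect_equal(sum(mb$counts), 0)
})

test_that("tallying conserves reads and matches conventions near bin edges", {
  grid <- make_bin_grid(c(chr1 = 10000))
  set.seed(1)
  n <- 500
  reads <- data.frame(chrom = "chr1",
                      pos = sample(0:9800, n, replace = TRUE),
                      width = sample(50:199, n, replace = TRUE),
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      mapq = 60, stringsAsFactors = FALSE)
  reads <- reads[reads$pos + reads$width <= 10000, ]
  m5 <- tally_reads(reads, grid, tally_config(mode = "five_prime_both"))
  md <- tally_reads(reads, grid, tally_config(mode = "distal"))
  expect_equal(sum(m5$counts), nrow(reads))     # each read in exactly 1 bin
  expect_equal(sum(md$counts), nrow(reads))
  # conventions agree for minus-strand reads, shift plus-strand reads by at
  # most one bin for reads shorter than the bin size
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    b5 <- if (r$strand == "+") r$pos %/% 1000 else
      (r$pos + r$width - 1) %/% 1000
    bd <- (r$pos + r$width - 1) %/% 1000
    if (r$strand == "-") expect_identical(b5, bd)
    else expect_lte(bd - b5, 1)
  }
})

test_that("tallying a BAM file agrees with tallying its records directly", {
  sam <- file.path(tempdir(), "toy.sam")
  # 4 reads: plus/minus pairs straddling a bin edge, one low-MAPQ
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:5000",
    "r1\t0\tchr1\t950\t60\t100M\t*\t0\t0\t*\t*",
    "r2\t16\tchr1\t950\t60\t100M\t*\t0\t0\t*\t*",
    "r3\t0\tchr1\t2000\t10\t100M\t*\t0\t0\t*\t*",
    "r4\t0\tchr1\t3001\t60\t50M20D30M\t*\t0\t0\t*\t*"), sam)
  bam <- Rsamtools::asBam(sam, file.path(tempdir(), "toy"),
                          overwrite = TRUE)
  grid <- make_bin_grid(c(chr1 = 5000))
  m <- tally_reads(bam, grid, tally_config(mq_min = 20), sample = "toy")
  expect_equal(sum(m$counts), 3)                 # r3 fails MAPQ
  # r1 plus: 5' = 949 -> bin 1; r2 minus: 5' = rightmost 1048 -> bin 2
  df <- data.frame(chrom = "chr1", pos = c(949, 949, 3000),
                   width = c(100, 100, 100), strand = c("+", "-", "+"),
                   mapq = 60, stringsAsFactors = FALSE)
  ref <- tally_reads(df, grid, tally_config(mq_min = 20), sample = "toy")
  expect_equal(m$counts, ref$counts)
  # deletion in r4's CIGAR extends its reference span to 100 bp
  expect_equal(which(m$counts[1, ] > 0), c(1L, 2L, 4L))
})

test_that("libraries combine by summing counts over aligned samples", {
  a <- cm_fixture(matrix(c(3, 1, 0, 2), 2, 2), samples = c("x", "y"))
  b0 <- matrix(c(5, 0, 1, 4), 2, 2)
  b <- cm_fixture(b0[2:1, ], samples = c("y", "x"))   # shuffled rows
  ab <- combine_libraries(a, b)
  expect_equal(ab$counts["x", ], a$counts["x", ] + b$counts["x", ])
  expect_equal(sum(ab$counts), sum(a$counts) + sum(b$counts))
  # identity and commutativity
  z <- cm_fixture(matrix(0, 2, 2), samples = c("x", "y"))
  expect_equal(combine_libraries(a, z)$counts, a$counts)
  ba <- combine_libraries(b, a)
  expect_equal(ab$counts[c("x", "y"), ], ba$counts[c("x", "y"), ])
  # sample mismatch names the difference
  c2 <- cm_fixture(matrix(1, 2, 2), samples = c("x", "zz"))
  expect_error(combine_libraries(a, c2), "zz")
})

test_that("count matrices round-trip through TSV", {
  m <- cm_fixture(matrix(c(0, 5, 2, 7, 1, 3, 9, 4), 2, 4),
                  samples = c("s1", "s2"))
  path <- file.path(tempdir(), "counts.tsv")
  write_count_matrix(m, path)
  m2 <- load_count_matrix(path)
  expect_equal(m2$counts, m$counts)
  expect_equal(m2$grid$bins, m$grid$bins)
  # gzip round-trip
  pgz <- file.path(tempdir(), "counts.tsv.gz")
  write_count_matrix(m, pgz)
  expect_equal(load_count_matrix(pgz)$counts, m$counts)
  # negative counts rejected
  writeLines(c("chrom\tstart\tend\ts1", "chr1\t1\t1000\t-3"),
             file.path(tempdir(), "neg.tsv"))
  expect_error(load_count_matrix(file.path(tempdir(), "neg.tsv")),
               "negative")
  # missing coordinate header rejected
  writeLines(c("foo\tbar", "1\t2"), file.path(tempdir(), "hdr.tsv"))
  expect_error(load_count_matrix(file.path(tempdir(), "hdr.tsv")),
               "chrom")
})
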