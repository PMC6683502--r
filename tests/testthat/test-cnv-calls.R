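test_that("segment means classify into CNV types with exact boundaries", {
  segs <- segs_fixture(means = c(-3, -1, 0.5, -0.4, 0.2, -2.5, -0.5, 0.21),
                       lengths = rep(10, 8))
  calls <- classify_segments(segs)
  # -3 homdel; -1 hetdel; 0.5 dup; -0.4 and 0.2 copy-neutral;
  # -2.5 hetdel (homdel strict <); -0.5 hetdel (closed); 0.21 dup (strict >)
  expect_equal(calls$type,
               c("homdel", "hetdel", "dup", "hetdel", "hetdel", "dup"))
  expect_equal(calls$mean_log2[1], -3)
  expect_equal(calls$n_bins, rep(10L, 6))
  # no segment gets two types and neutral gap yields none
  expect_equal(nrow(classify_segments(segs_fixture(0.1, 10))), 0)
})

test_that("support filtering enforces per-type bin minima", {
  calls <- data.frame(sample = "s", type = c("homdel", "homdel", "dup",
                                             "dup", "hetdel"),
                      chrom = "c", first_bin = 1, last_bin = 1,
                      n_bins = c(2, 3, 5, 6, 7), mean_log2 = -3,
                      dataset = "mq20", stringsAsFactors = FALSE)
  kept <- filter_support(calls, class_thresholds())
  expect_equal(kept$n_bins, c(3, 6, 7))
  # relaxed preset keeps a 2-bin homozygous deletion
  relaxed <- class_thresholds(min_bins_homdel = 1, min_bins_hetdup = 2)
  expect_equal(nrow(filter_support(calls, relaxed)), 5)
})

test_that("contiguous same-type calls merge with weighted means", {
  mk <- function(type, fb, lb, mean) {
    data.frame(sample = "s", type = type, chrom = "c", first_bin = fb,
               last_bin = lb, n_bins = lb - fb + 1, mean_log2 = mean,
               dataset = "mq20", stringsAsFactors = FALSE)
  }
  # consecutive homdels merge; weighted mean; bins summed
  m <- merge_contiguous(rbind(mk("homdel", 1, 2, -3), mk("homdel", 3, 5, -4)))
  expect_equal(nrow(m), 1)
  expect_equal(m$n_bins, 5)
  expect_equal(m$mean_log2, (2 * -3 + 3 * -4) / 5)
  # different types never merge
  m2 <- merge_contiguous(rbind(mk("homdel", 1, 2, -3), mk("hetdel", 3, 5, -1)))
  expect_equal(nrow(m2), 2)
  # one intervening informative bin breaks contiguity
  m3 <- merge_contiguous(rbind(mk("homdel", 1, 2, -3), mk("homdel", 4, 6, -3)))
  expect_equal(nrow(m3), 2)
})

test_that("minimum and maximum spans follow the supporting-bin convention", {
  r <- rm_fixture(c(7000, 10000, 14000, 18000), chrom_len = 30000)
  call <- data.frame(sample = "s1", type = "homdel", chrom = "chr1",
                     first_bin = 2, last_bin = 3, n_bins = 2,
                     mean_log2 = -3, dataset = "mq20",
                     stringsAsFactors = FALSE)
  sp <- compute_spans(call, r)
  expect_equal(c(sp$min_start, sp$min_end), c(11000, 14000))
  expect_equal(c(sp$max_start, sp$max_end), c(7000, 19000))
  expect_equal(sp$size_kbp, 3)
  expect_false(sp$degenerate_span)
  # chromosome edges substitute for missing flanks
  edge <- call; edge$first_bin <- 1; edge$last_bin <- 4
  spe <- compute_spans(edge, r)
  expect_equal(spe$max_start, 0)
  expect_equal(spe$max_end, 30000)
  # a single supporting bin yields an empty, flagged minimum span
  one <- call; one$first_bin <- 2; one$last_bin <- 2; one$n_bins <- 1
  spo <- compute_spans(one, r)
  expect_true(spo$degenerate_span)
  expect_equal(spo$size_kbp, 0)
})

test_that("calls overlapping exclusion regions are removed by >= 1 bp", {
  calls <- data.frame(sample = "s", type = "homdel", chrom = "chr1",
                      first_bin = 1, last_bin = 2, n_bins = 2,
                      mean_log2 = -3, dataset = "mq20",
                      max_start = c(5000, 20000), max_end = c(9000, 24000),
                      min_start = c(6000, 21000), min_end = c(8000, 23000),
                      stringsAsFactors = FALSE)
  ex <- data.frame(chrom = "chr1", start = 8999, end = 12000)
  kept <- exclude_regions(calls, ex)
  expect_equal(kept$max_start, 20000)     # 1-bp overlap removed the first
  expect_equal(nrow(exclude_regions(calls, NULL)), 2)
  expect_equal(nrow(exclude_regions(calls, ex[0, ])), 2)
  ex2 <- data.frame(chrom = "chr1", start = 9000, end = 12000)
  expect_equal(nrow(exclude_regions(calls, ex2)), 2)  # abutting, no overlap
})

test_that("the full pipeline recovers a planted homozygous deletion", {
  ev <- data.frame(sample = "S003", type = "homdel", chrom = "Chr02",
                   start = 1.2e6, end = 1.3e6, copy_multiplier = 0,
                   stringsAsFactors = FALSE)
  sim <- simulate_population(sim_config(seed = 42, events = ev),
                             acgh = FALSE)
  calls <- call_cnvs(sim$lib1, sim$lib1)
  hom <- calls[calls$type == "homdel", ]
  expect_equal(nrow(hom), 1)
  expect_equal(hom$sample, "S003")
  expect_equal(hom$chrom, "Chr02")
  expect_lte(hom$max_start, 1.2e6)
  expect_gte(hom$max_end, 1.3e6)
  expect_lt(hom$mean_log2, -2.5)
  # determinism: identical inputs and config give identical call tables
  calls2 <- call_cnvs(sim$lib1, sim$lib1)
  expect_identical(as.data.frame(calls), as.data.frame(calls2))
})

test_that("the hetdel dataset feeds hetdels, the other dataset the rest", {
  ev <- data.frame(sample = c("S001", "S002"), type = c("homdel", "hetdel"),
                   chrom = c("Chr01", "Chr03"), start = c(1e6, 7.0e6),
                   end = c(1.15e6, 8.0e6), copy_multiplier = c(0, 0.5),
                   stringsAsFactors = FALSE)
  sim <- simulate_population(sim_config(seed = 43, events = ev),
                             acgh = FALSE)
  calls <- call_cnvs(sim$lib1, sim$lib2)
  expect_true(all(calls$dataset[calls$type == "hetdel"] == "mq35"))
  expect_true(all(calls$dataset[calls$type != "hetdel"] == "mq20"))
  # excluded samples contribute nothing
  calls2 <- call_cnvs(sim$lib1, sim$lib2, excluded_samples = "S001")
  expect_false("S001" %in% calls2$sample)
})

test_that("sample QC flags shallow samples and call-count outliers", {
  set.seed(9)
  counts <- matrix(rpois(10 * 50, 20), 10, 50)
  counts[7, ] <- rpois(50, 1)                   # ~5% of median depth
  m <- cm_fixture(counts)
  calls <- data.frame(sample = c(rep("s2", 30), "s5", "s9"),
                      stringsAsFactors = FALSE)
  qc <- sample_qc(calls, m)
  expect_true(qc$low_depth[7])
  expect_false(any(qc$low_depth[-7]))
  expect_true(qc$excess_calls[qc$sample == "s2"])   # 30 calls vs median 0
  expect_false(qc$excess_calls[qc$sample == "s9"])
  # identical samples: nothing flagged
  qc2 <- sample_qc(calls[0, , drop = FALSE], cm_fixture(matrix(10, 4, 5)))
  expect_false(any(qc2$low_depth | qc2$excess_calls))
})

test_that("relaxed stringency recovers every default-preset call", {
  ev <- data.frame(sample = c("S001", "S004"), type = "homdel",
                   chrom = c("Chr01", "Chr04"), start = c(1e6, 7.5e6),
                   end = c(1.1e6, 7.62e6), copy_multiplier = 0,
                   stringsAsFactors = FALSE)
  sim <- simulate_population(sim_config(seed = 44, events = ev),
                             acgh = FALSE)
  strict <- call_cnvs(sim$lib1, sim$lib1, pipeline_params("strict"))
  relaxed <- call_cnvs(sim$lib1, sim$lib1, pipeline_params("relaxed"))
  expect_gte(nrow(relaxed), nrow(strict))
  # every strict call is rediscovered (same sample/type, overlapping span)
  for (i in seq_len(nrow(strict))) {
    hit <- relaxed$sample == strict$sample[i] &
      relaxed$type == strict$type[i] &
      relaxed$chrom == strict$chrom[i] &
      relaxed$max_start < strict$max_end[i] &
      relaxed$max_end > strict$max_start[i]
    expect_true(any(hit))
  }
})

test_that("call tables export to CSV and BED and read back", {
  ev <- data.frame(sample = "S002", type = "homdel", chrom = "Chr01",
                   start = 2e6, end = 2.2e6, copy_multiplier = 0,
                   stringsAsFactors = FALSE)
  sim <- simulate_population(sim_config(seed = 45, events = ev),
                             acgh = FALSE)
  calls <- call_cnvs(sim$lib1, sim$lib1)
  csv <- file.path(tempdir(), "calls.csv")
  write_cnv_csv(calls, csv)
  back <- load_truth_table(csv)
  expect_equal(nrow(back), nrow(calls))
  expect_equal(back$start, calls$min_start)     # 1-based CSV -> 0-based
  expect_equal(back$end, calls$min_end)
  bed <- file.path(tempdir(), "calls.bed")
  write_cnv_bed(calls, bed)
  b <- read.table(bed, sep = "\t")
  expect_equal(b[[2]], calls$min_start)
  expect_equal(b[[5]], round(-10 * calls$mean_log2))
})
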