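gbs_row <- function(sample, type, chrom, min_s, min_e, max_s, max_e) {
  data.frame(sample = sample, type = type, chrom = chrom,
             min_start = min_s, min_end = min_e,
             max_start = max_s, max_end = max_e, stringsAsFactors = FALSE)
}
truth_row <- function(sample, type, chrom, start, end) {
  data.frame(sample = sample, type = type, chrom = chrom, start = start,
             end = end, stringsAsFactors = FALSE)
}

test_that("event matching follows the same-sample same-type overlap rule", {
  gbs <- rbind(gbs_row("m1", "homdel", "c1", 110e3, 150e3, 100e3, 160e3),
               gbs_row("m1", "hetdel", "c2", 10e3, 20e3, 5e3, 25e3),
               gbs_row("m2", "homdel", "c1", 110e3, 150e3, 100e3, 160e3))
  truth <- rbind(truth_row("m1", "homdel", "c1", 90e3, 170e3),
                 truth_row("m1", "homdel", "c2", 5e3, 25e3),   # type differs
                 truth_row("m3", "dup", "c3", 1e3, 50e3))
  mr <- match_events(gbs, truth)
  expect_equal(mr$gbs$status,
               c("true_positive", "false_positive", "false_positive"))
  # m2's call overlaps m1's truth interval but samples differ
  expect_equal(mr$truth$status, c("detected", "undetected", "undetected"))
  # conservation laws
  expect_equal(mr$n_true_positive + mr$n_false_positive, nrow(gbs))
  expect_equal(mr$n_detected + mr$n_undetected, nrow(truth))
})

test_that("split and merged correspondences are labeled", {
  gbs <- rbind(gbs_row("m1", "homdel", "c1", 110e3, 130e3, 100e3, 140e3),
               gbs_row("m1", "homdel", "c1", 150e3, 170e3, 145e3, 180e3),
               gbs_row("m2", "homdel", "c1", 10e3, 90e3, 5e3, 95e3))
  truth <- rbind(truth_row("m1", "homdel", "c1", 100e3, 180e3),
                 truth_row("m2", "homdel", "c1", 10e3, 40e3),
                 truth_row("m2", "homdel", "c1", 60e3, 90e3))
  mr <- match_events(gbs, truth)
  expect_equal(sort(mr$links$relation[mr$links$truth_idx == 1]),
               c("split", "split"))
  expect_equal(unique(mr$links$relation[mr$links$gbs_idx == 3]), "merged")
  expect_equal(mr$n_detected, 3)
  expect_equal(mr$n_false_positive, 0)
})

test_that("size agreement reports span percentages and adjusted R2", {
  # perfect agreement: 100 / 100 / R2 = 1
  n <- 5
  sizes <- c(30e3, 60e3, 120e3, 240e3, 480e3)
  gbs <- do.call(rbind, lapply(seq_len(n), function(i)
    gbs_row("m1", "homdel", paste0("c", i), 0, sizes[i], 0, sizes[i])))
  truth <- do.call(rbind, lapply(seq_len(n), function(i)
    truth_row("m1", "homdel", paste0("c", i), 0, sizes[i])))
  # lm warns about the essentially perfect fit; the statistic is exact
  sa <- suppressWarnings(size_agreement(match_events(gbs, truth)))
  expect_equal(sa$mean_min_pct, 100)
  expect_equal(sa$mean_max_pct, 100)
  expect_equal(sa$adj_r2, 1)
  expect_equal(sa$n, 5L)

  # two pairs: percentages by arithmetic, adjusted R2 undefined (n < 4)
  gbs2 <- rbind(gbs_row("m1", "homdel", "c1", 0, 80e3, 0, 160e3),
                gbs_row("m1", "homdel", "c2", 0, 90e3, 0, 130e3))
  truth2 <- rbind(truth_row("m1", "homdel", "c1", 0, 100e3),
                  truth_row("m1", "homdel", "c2", 0, 100e3))
  sa2 <- size_agreement(match_events(gbs2, truth2))
  expect_equal(sa2$mean_min_pct, 85)
  expect_equal(sa2$mean_max_pct, 145)
  expect_true(is.na(sa2$adj_r2))

  # adjusted R2 agrees with the closed form computed by hand
  set.seed(77)
  sizes <- exp(runif(8, log(3e4), log(2e6)))
  minl <- sizes * runif(8, 0.7, 0.95)
  maxl <- sizes * runif(8, 1.1, 1.8)
  gbs3 <- do.call(rbind, lapply(1:8, function(i)
    gbs_row("m1", "homdel", paste0("c", i), 0, minl[i], 0, maxl[i])))
  truth3 <- do.call(rbind, lapply(1:8, function(i)
    truth_row("m1", "homdel", paste0("c", i), 0, sizes[i])))
  sa3 <- size_agreement(match_events(gbs3, truth3))
  X <- cbind(1, log10(minl), log10(maxl))
  yv <- log10(sizes)
  bhat <- solve(t(X) %*% X, t(X) %*% yv)
  r2 <- 1 - sum((yv - X %*% bhat)^2) / sum((yv - mean(yv))^2)
  expect_equal(sa3$adj_r2, 1 - (1 - r2) * (8 - 1) / (8 - 3),
               tolerance = 1e-10)
})

test_that("detection-by-size tabulates statuses and extremes", {
  gbs <- gbs_row("m1", "homdel", "c1", 10e3, 60e3, 5e3, 65e3)
  truth <- rbind(truth_row("m1", "homdel", "c1", 10e3, 60e3),
                 truth_row("m1", "homdel", "c2", 100e3, 220e3),  # 120 kb miss
                 truth_row("m1", "hetdel", "c3", 0, 40e3))
  db <- detection_by_size(match_events(gbs, truth))
  expect_equal(sum(db$table[, , "undetected"]), 2)
  expect_equal(db$extremes$homdel$smallest_detected_kbp, 50)
  expect_equal(db$extremes$homdel$largest_undetected_kbp, 120)
  # all detected: undetected column all zero
  db2 <- detection_by_size(match_events(gbs, truth[1, ]))
  expect_equal(sum(db2$table[, , "undetected"]), 0)
})

test_that("ddPCR copy numbers follow diploid-scaled arithmetic", {
  expect_equal(ddpcr_copy_number(2.2, 2.2), 2)
  expect_equal(ddpcr_copy_number(1.1, 2.2), 1)
  expect_equal(ddpcr_copy_number(0, 5), 0)
  # scale invariance
  expect_equal(ddpcr_copy_number(3.3, 1.1), ddpcr_copy_number(33, 11))
  expect_error(ddpcr_copy_number(1, 0), "positive")
})

test_that("ddPCR verdicts implement the validation bands", {
  # the canonical outcomes
  expect_equal(ddpcr_validate(0, 2, "hetdel"), "reclassified_homdel")
  expect_equal(ddpcr_validate(2 * 1.07, 2, "hetdel"), "false_positive")
  expect_equal(ddpcr_validate(2 * 0.56, 2, "hetdel"), "validated")
  expect_equal(ddpcr_validate(4, 2, "dup"), "validated")
  expect_equal(ddpcr_validate(2, 2, "dup"), "false_positive")
  expect_equal(ddpcr_validate(0.05, 2, "homdel"), "validated")
  expect_equal(ddpcr_validate(2.1, 2, "homdel"), "false_positive")
  # control far from two copies per locus: inconclusive
  expect_equal(ddpcr_validate(5, 11, "dup"), "inconclusive")
  # unless the multiplicity accounts for it
  expect_equal(ddpcr_validate(6, 12, "hetdel", multiplicity = 6),
               "validated")
  expect_error(ddpcr_validate(1, 2, "inversion"), "claimed_type")
})

test_that("ddPCR assay tables load and annotate", {
  path <- file.path(tempdir(), "ddpcr.csv")
  writeLines(c(paste0("ID,CNV_type,chr,start,end,primer_pair,mutant_conc,",
                      "mutant_ref,control_conc,control_ref"),
               "FN1,hetdel,chr1,1,10,P1,5.5,11,11,11",
               "FN2,dup,chr2,1,10,P2,22,11,11,11"), path)
  df <- load_ddpcr_table(path)
  expect_equal(df$mutant_n, c(1, 4))
  expect_equal(df$control_n, c(2, 2))
  expect_equal(df$ratio, c(0.5, 2))
  expect_equal(ddpcr_validate(df$mutant_n, df$control_n, df$CNV_type),
               c("validated", "validated"))
})

test_that("gene-overlap totals count each disruption once per event", {
  genes <- data.frame(chrom = c("c1", "c1", "c2", "c2", "c2"),
                      start = c(10e3, 50e3, 1e3, 2e3, 3e3),
                      end = c(12e3, 55e3, 1500, 2500, 3500),
                      id = paste0("g", 1:5), stringsAsFactors = FALSE)
  calls <- rbind(gbs_row("m1", "homdel", "c1", 9e3, 13e3, 8e3, 14e3),
                 gbs_row("m2", "homdel", "c1", 11e3, 20e3, 10e3, 21e3),
                 gbs_row("m1", "dup", "c2", 0, 4e3, 0, 5e3))
  tot <- count_affected_genes(calls, genes)
  # g1 hit by homdels in two lines counts twice; 3 genes inside one dup
  expect_equal(tot, c(homdel = 2, hetdel = 0, dup = 3))
  # adjacent but non-overlapping gene contributes nothing
  calls2 <- gbs_row("m1", "homdel", "c1", 12e3, 50e3, 9e3, 51e3)
  expect_equal(count_affected_genes(calls2, genes)[["homdel"]], 0)
  # additive over disjoint call subsets
  expect_equal(tot,
               count_affected_genes(calls[1:2, ], genes) +
                 count_affected_genes(calls[3, ], genes))
  # max-span mode widens the overlap to both flanking genes
  expect_equal(count_affected_genes(calls2, genes, span = "max")[["homdel"]],
               2)
})
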