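# shared fixtures and independent oracles

# count_matrix over a single-chromosome grid, one bin per column
cm_fixture <- function(counts, bin_size = 1000, chrom = "chr1",
                       normalized = FALSE, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(nrow(counts)))
  grid <- make_bin_grid(stats::setNames(ncol(counts) * bin_size, chrom),
                        bin_size)
  count_matrix(counts, grid, samples, normalized = normalized)
}

# minimal ratio_matrix: informative bins at given starts on one chromosome
rm_fixture <- function(starts, chrom = "chr1", chrom_len = NULL,
                       bin_size = 1000) {
  if (is.null(chrom_len)) chrom_len <- max(starts) + 10 * bin_size
  grid <- make_bin_grid(stats::setNames(chrom_len, chrom), bin_size)
  bins <- data.frame(chrom = chrom, start = starts, end = starts + bin_size,
                     grid_index = starts / bin_size + 1, stringsAsFactors = FALSE)
  structure(list(samples = "s1", bins = bins,
                 ratios = matrix(0, 1, length(starts),
                                 dimnames = list("s1", NULL)),
                 bin_means = rep(10, length(starts)), grid = grid),
            class = "ratio_matrix")
}

# fake segment_all() output: one sample, one chromosome, given segment
# means and lengths
segs_fixture <- function(means, lengths, sample = "s1", chrom = "chr1") {
  ends <- cumsum(lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  sg <- structure(list(starts = as.integer(starts), ends = as.integer(ends),
                       boundaries = as.integer(head(ends, -1)),
                       segment_means = means, objective = 0,
                       n = sum(lengths)), class = "segmentation")
  out <- stats::setNames(list(stats::setNames(list(sg), chrom)), sample)
  out
}

# independent exact biweight segment cost: knot sweep written in plain R,
# sharing no code with the C++ engine
bw_cost_oracle <- function(y, K) {
  knots <- sort(unique(c(y - K, y + K)))
  f <- function(th) sum(pmin((y - th)^2, K^2))
  best <- min(vapply(knots, f, 0))
  for (iv in seq_len(length(knots) - 1)) {
    o <- stats::optimize(f, c(knots[iv], knots[iv + 1]))
    best <- min(best, o$objective)
  }
  best
}

# brute-force optimum over all 2^(n-1) segmentations (n <= 12)
brute_force_objective <- function(y, beta, K) {
  n <- length(y)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cps <- if (n > 1) which(bitwAnd(bitwShiftR(mask, 0:(n - 2)), 1) == 1)
      else integer()
    starts <- c(1, cps + 1)
    ends <- c(cps, n)
    cost <- sum(mapply(function(s, e) bw_cost_oracle(y[s:e], K),
                       starts, ends)) + beta * length(cps)
    best <- min(best, cost)
  }
  best
}

# planted-event designs used by the simulation tests; events sit in the
# euchromatic arms (0-3 Mb and 7-10 Mb of each 10-Mb chromosome)
recovery_events <- function() {
  data.frame(
    sample = sprintf("S%03d", 1:10),
    type = c(rep("homdel", 4), rep("hetdel", 3), rep("dup", 3)),
    chrom = c("Chr01", "Chr02", "Chr03", "Chr04", "Chr01", "Chr02",
              "Chr05", "Chr03", "Chr04", "Chr05"),
    start = c(0.5e6, 1.5e6, 7.5e6, 2.0e6, 1.0e6, 7.0e6, 0.3e6,
              0.5e6, 7.0e6, 1.0e6),
    end = c(0.5e6 + 60e3, 1.5e6 + 100e3, 7.5e6 + 150e3, 2.0e6 + 250e3,
            1.0e6 + 800e3, 7.0e6 + 1000e3, 0.3e6 + 1200e3,
            0.5e6 + 2000e3, 7.0e6 + 2500e3, 1.0e6 + 2000e3),
    copy_multiplier = c(rep(0, 4), rep(0.5, 3), rep(2, 3)),
    stringsAsFactors = FALSE)
}

# one replicate: simulate, call, match; returns per-event detection with
# informative-bin coverage plus false-positive table
run_recovery_rep <- function(seed, events, params = pipeline_params(),
                             matrix_fun = function(sim) sim$lib1) {
  sim <- simulate_population(sim_config(seed = seed, events = events),
                             acgh = FALSE)
  m <- matrix_fun(sim)
  calls <- call_cnvs(m, m, params)
  mr <- match_events(calls, sim$truth$events)
  r20 <- attr(calls, "ratios")$mq20
  r35 <- attr(calls, "ratios")$mq35
  cov <- ifelse(events$type == "hetdel",
                event_bin_coverage(events, r35),
                event_bin_coverage(events, r20))
  list(truth = cbind(mr$truth, cov = cov),
       gbs = mr$gbs, links = mr$links, match = mr, calls = calls)
}
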