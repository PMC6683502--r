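#' Simulation configuration
#'
#' Describes a synthetic GBS study: a mutant population genotyped by
#' restriction-site sequencing, with informative sites dense in euchromatin
#' and sparse in a centered pericentromeric block (emulating a
#' methylation-sensitive enzyme that rarely cuts heterochromatin), two
#' size-selection libraries sharing a configurable fraction of sites,
#' per-sample depth variation, negative-binomial count noise, and planted
#' CNVs.
#'
#' @param seed Integer RNG seed; every draw derives from it.
#' @param n_samples Number of samples (default 24).
#' @param chromosomes Named vector of chromosome lengths in bp (default
#'   5 chromosomes of 10 Mb).
#' @param bin_size Bin width in bp (default 1000).
#' @param site_density_euchromatin,site_density_pericentromere Informative
#'   sites per 10 kb (defaults 2 and 0.2).
#' @param pericentromere_fraction Fraction of each chromosome occupied by
#'   the centered pericentromeric block (default 0.4).
#' @param depth_mean Expected reads per informative site (default 12).
#' @param depth_sample_sd_log Log-normal sd of per-sample depth factors
#'   (default 0.3; factors have mean 1).
#' @param nb_dispersion Negative-binomial overdispersion: count variance is
#'   `mu + nb_dispersion * mu^2`; 0 degenerates to Poisson (default 0.15).
#' @param library_overlap_fraction Share of sites present in both libraries
#'   (default 0.5); the rest split evenly between library-exclusive sets.
#' @param events Planted CNVs: data.frame with columns `sample`, `type`
#'   (`homdel`/`hetdel`/`dup`), `chrom`, `start`, `end` (0-based half-open)
#'   and `copy_multiplier` (0 for homdel, 0.5 for hetdel, >= 1.5 for dup).
#' @param mismap_rate Residual expected reads (fraction of `depth_mean`) in
#'   homozygously deleted sites, emulating mismapping background; default 0,
#'   so the deletion log2 ratio arises purely from the +1 pseudo-count.
#' @param acgh_probe_spacing Probe spacing in bp for the synthetic aCGH
#'   profiles (default 1000).
#' @param acgh_noise_sd Gaussian probe noise sd in log2 units (default 0.3).
#' @param acgh_homdel_level Probe log2 level inside homozygous deletions
#'   (default -4; other events sit at `log2(copy_multiplier)`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_samples = 24,
                       chromosomes = stats::setNames(rep(1e7, 5),
                         sprintf("Chr%02d", 1:5)),
                       bin_size = 1000,
                       site_density_euchromatin = 2,
                       site_density_pericentromere = 0.2,
                       pericentromere_fraction = 0.4,
                       depth_mean = 12, depth_sample_sd_log = 0.3,
                       nb_dispersion = 0.15,
                       library_overlap_fraction = 0.5,
                       events = NULL, mismap_rate = 0,
                       acgh_probe_spacing = 1000, acgh_noise_sd = 0.3,
                       acgh_homdel_level = -4) {
  if (site_density_euchromatin <= 0 || site_density_pericentromere <= 0)
    stop("site densities must be positive")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (library_overlap_fraction < 0 || library_overlap_fraction > 1)
    stop("library_overlap_fraction must be in [0, 1]")
  if (is.null(events))
    events <- data.frame(sample = character(), type = character(),
                         chrom = character(), start = numeric(),
                         end = numeric(), copy_multiplier = numeric(),
                         stringsAsFactors = FALSE)
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_events(cfg)
  cfg
}

validate_sim_events <- function(cfg) {
  ev <- cfg$events
  if (nrow(ev) == 0) return(invisible(TRUE))
  lens <- cfg$chromosomes
  if (any(!(ev$chrom %in% names(lens))))
    stop("event on unknown chromosome")
  if (any(ev$start < 0 | ev$end > lens[ev$chrom] | ev$start >= ev$end))
    stop("events must lie within chromosome bounds with start < end")
  bad_mult <- (ev$type == "homdel" & ev$copy_multiplier != 0) |
    (ev$type == "hetdel" & ev$copy_multiplier != 0.5) |
    (ev$type == "dup" & ev$copy_multiplier < 1.5)
  if (any(bad_mult))
    stop("copy_multiplier must be 0 (homdel), 0.5 (hetdel) or >= 1.5 (dup)")
  # overlapping same-sample events with different multipliers contradict
  for (s in unique(ev$sample)) {
    for (ch in unique(ev$chrom[ev$sample == s])) {
      e <- ev[ev$sample == s & ev$chrom == ch, , drop = FALSE]
      if (nrow(e) < 2) next
      o <- order(e$start)
      e <- e[o, ]
      ovl <- which(e$start[-1] < e$end[-nrow(e)])
      if (any(e$copy_multiplier[ovl] != e$copy_multiplier[ovl + 1]))
        stop("overlapping events with contradictory multipliers for sample ",
             s)
    }
  }
  invisible(TRUE)
}

# run expr with the RNG seeded to `seed`, restoring the caller's RNG state
with_sim_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a GBS-screened mutant population
#'
#' Draws informative sites from an inhomogeneous Poisson process with the
#' euchromatin / pericentromere density regimes, assigns each site to
#' library 1, library 2, or both, applies planted CNV multipliers, and draws
#' per-bin negative-binomial read counts for every sample.  Optionally emits
#' matching synthetic aCGH probe profiles.  Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param acgh Also generate synthetic aCGH probe profiles for every sample
#'   (default `TRUE`; disable in tight simulation loops).
#' @return A list with `lib1`, `lib2` (raw `count_matrix` objects), `acgh`
#'   (probe data.frame or `NULL`), and `truth` (class `sim_truth`: `events`
#'   with an added `id`, `sites` per library, and `expected_mean` per-bin
#'   population expectations per library).
#' @export
simulate_population <- function(cfg = sim_config(), acgh = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_events(cfg)
  with_sim_seed(cfg$seed, {
    grid <- make_bin_grid(cfg$chromosomes, cfg$bin_size)
    samples <- sprintf("S%03d", seq_len(cfg$n_samples))

    # informative sites: two density regimes, pericentromere centered
    sites <- do.call(rbind, lapply(names(cfg$chromosomes), function(ch) {
      len <- cfg$chromosomes[[ch]]
      peri_half <- len * cfg$pericentromere_fraction / 2
      p0 <- len / 2 - peri_half; p1 <- len / 2 + peri_half
      lam_eu <- cfg$site_density_euchromatin / 1e4
      lam_pc <- cfg$site_density_pericentromere / 1e4
      n_eu <- rpois(1, lam_eu * (len - (p1 - p0)))
      n_pc <- rpois(1, lam_pc * (p1 - p0))
      pos_eu <- runif(n_eu, 0, len - (p1 - p0))
      pos_eu <- ifelse(pos_eu < p0, pos_eu, pos_eu + (p1 - p0))
      pos_pc <- runif(n_pc, p0, p1)
      data.frame(chrom = ch, pos = floor(sort(c(pos_eu, pos_pc))),
                 stringsAsFactors = FALSE)
    }))
    u <- runif(nrow(sites))
    f <- cfg$library_overlap_fraction
    sites$lib1 <- u < f | (u >= f & u < f + (1 - f) / 2)
    sites$lib2 <- u < f | u >= f + (1 - f) / 2
    sites$bin <- bin_index(grid, sites$chrom, sites$pos)

    sample_factor <- rlnorm(cfg$n_samples,
                            meanlog = -cfg$depth_sample_sd_log^2 / 2,
                            sdlog = cfg$depth_sample_sd_log)

    ev <- cfg$events
    site_mult <- function(s) {
      mult <- rep(1, nrow(sites))
      if (nrow(ev) == 0) return(mult)
      es <- ev[ev$sample == s, , drop = FALSE]
      for (k in seq_len(nrow(es))) {
        inside <- sites$chrom == es$chrom[k] & sites$pos >= es$start[k] &
          sites$pos < es$end[k]
        m <- es$copy_multiplier[k]
        if (m == 0 && cfg$mismap_rate > 0) m <- cfg$mismap_rate
        mult[inside] <- m
      }
      mult
    }

    draw_counts <- function(lib_mask) {
      bins_of_sites <- sites$bin[lib_mask]
      counts <- matrix(0, nrow = cfg$n_samples, ncol = length(grid),
                       dimnames = list(samples, NULL))
      for (i in seq_len(cfg$n_samples)) {
        mult <- site_mult(samples[i])[lib_mask]
        mu_site <- cfg$depth_mean * sample_factor[i] * mult
        mu_bin <- tapply(mu_site, bins_of_sites, sum)
        idx <- as.integer(names(mu_bin))
        mu <- as.numeric(mu_bin)
        draw <- if (cfg$nb_dispersion > 0)
          rnbinom(length(mu), size = 1 / cfg$nb_dispersion, mu = mu)
        else rpois(length(mu), mu)
        counts[i, idx] <- draw
      }
      counts
    }
    lib1 <- count_matrix(draw_counts(sites$lib1), grid, samples,
                         library_id = "lib1",
                         tally = tally_config(mode = "five_prime_both"))
    lib2 <- count_matrix(draw_counts(sites$lib2), grid, samples,
                         library_id = "lib2",
                         tally = tally_config(mode = "distal"))

    expected_mean <- function(lib_mask) {
      em <- numeric(length(grid))
      tb <- tapply(rep(cfg$depth_mean, sum(lib_mask)), sites$bin[lib_mask],
                   sum)
      em[as.integer(names(tb))] <- as.numeric(tb)
      em
    }

    acgh_df <- NULL
    if (acgh) {
      probes <- do.call(rbind, lapply(names(cfg$chromosomes), function(ch) {
        len <- cfg$chromosomes[[ch]]
        st <- seq(0, len - cfg$acgh_probe_spacing,
                  by = cfg$acgh_probe_spacing)
        data.frame(chrom = ch, start = st, end = st + 60,
                   stringsAsFactors = FALSE)
      }))
      acgh_df <- do.call(rbind, lapply(samples, function(s) {
        lev <- rep(0, nrow(probes))
        es <- ev[ev$sample == s, , drop = FALSE]
        for (k in seq_len(nrow(es))) {
          inside <- probes$chrom == es$chrom[k] &
            probes$start >= es$start[k] & probes$start < es$end[k]
          lev[inside] <- if (es$type[k] == "homdel") cfg$acgh_homdel_level
            else log2(es$copy_multiplier[k])
        }
        data.frame(sample = s, probes,
                   log2_ratio = lev + rnorm(nrow(probes), 0,
                                            cfg$acgh_noise_sd),
                   stringsAsFactors = FALSE)
      }))
    }

    events_out <- ev
    if (nrow(events_out) > 0)
      events_out$id <- sprintf("EV%03d", seq_len(nrow(events_out)))
    truth <- structure(list(events = events_out, sites = sites,
                            expected_mean = list(
                              lib1 = expected_mean(sites$lib1),
                              lib2 = expected_mean(sites$lib2)),
                            sample_factor = stats::setNames(sample_factor,
                                                            samples)),
                       class = "sim_truth")
    list(lib1 = lib1, lib2 = lib2, acgh = acgh_df, truth = truth)
  })
}

#' Thin a count matrix to a fraction of its depth
#'
#' Binomial thinning: each read is retained independently with probability
#' `fraction`, emulating a shallower sequencing run of the same library.
#'
#' @param m A raw integer `count_matrix`.
#' @param fraction Retention probability in (0, 1].
#' @param seed RNG seed.
#' @return A `count_matrix` of thinned counts.
#' @export
subsample_depth <- function(m, fraction, seed = 1) {
  stopifnot(inherits(m, "count_matrix"))
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (any(m$counts != round(m$counts)))
    stop("subsample_depth needs integer counts")
  if (fraction == 1) return(m)
  with_sim_seed(seed, {
    thinned <- m$counts
    nz <- which(thinned > 0)
    thinned[nz] <- rbinom(length(nz), size = as.integer(thinned[nz]),
                          prob = fraction)
    count_matrix(thinned, m$grid, m$samples, library_id = m$library_id,
                 tally = m$tally)
  })
}

#' Informative-bin coverage of planted events
#'
#' For each planted event, counts how many informative bins (those selected
#' by a [filter_bins()] mask) lie within the event interval -- the quantity
#' that determines whether the event is recoverable at a given support
#' minimum.
#'
#' @param truth A `sim_truth` (or its `events` data.frame).
#' @param r A `ratio_matrix` (its `bins` are the informative bins).
#' @return Integer vector, one count per event.
#' @export
event_bin_coverage <- function(truth, r) {
  ev <- if (inherits(truth, "sim_truth")) truth$events else truth
  if (nrow(ev) == 0) return(integer())
  vapply(seq_len(nrow(ev)), function(k) {
    sum(r$bins$chrom == ev$chrom[k] & r$bins$start >= ev$start[k] &
          r$bins$end <= ev$end[k])
  }, 0L)
}
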