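---
title: "Calling copy number variants from GBS read counts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling copy number variants from GBS read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbscnv)
```

## The problem and the signal

Irradiation mutagenesis (fast neutrons and similar) produces lesions from
point mutations up to multi-megabase deletions and duplications. Screening
a population of such mutants requires a genome-wide, per-individual map of
copy number, but arrays (aCGH) and whole-genome sequencing are too costly
at population scale. Genotyping-by-sequencing (GBS) reduces the genome to
restriction fragments — with a methylation-sensitive enzyme, mostly in
gene-rich euchromatin — and sequences them at useful depth even in 96-plex
libraries. The copy-number signal is relative read depth: in a genomic bin
covered by a restriction site, an individual carrying a deletion
contributes about half (hemizygous) or none (homozygous) of the reads its
cohort contributes, and a duplication proportionally more.

`gbscnv` turns that signal into typed CNV calls through a fixed sequence
of steps, each exposed as a function so intermediate results can be
inspected: tally reads into bins, normalize across samples, filter bins,
compute log2 ratios, segment, classify, filter by support, merge, compute
spans, and apply exclusion regions.

## Counting and tallying

The genome (nuclear chromosomes only; organellar and scaffold sequences
are deliberately absent from the bin grid so that reads aligned there are
dropped) is tiled into 1-kb bins (`make_bin_grid()`). A read increments
exactly one bin, chosen by one of two conventions (`tally_config()`):

* `five_prime_both` — the read's 5′ reference coordinate on either strand.
  Appropriate for short fragments, where both strands' reads start at the
  same cut site: paired conventions keep a fragment's reads in one bin.
* `distal` — the 3′ coordinate for plus-strand reads and the 5′ coordinate
  for minus-strand reads, i.e. the rightmost aligned base on both strands.
  Appropriate for longer-fragment libraries, where the 5′ convention
  could split a fragment's reads across a bin boundary.

Coordinates come from the aligned span on the reference (CIGAR-derived;
soft clips excluded). Unmapped, secondary, supplementary and
duplicate-flagged records are ignored, as are reads below the
mapping-quality threshold — MAPQ ≥ 20 for the dataset used to call
homozygous deletions and duplications, MAPQ ≥ 35 for hemizygous
deletions, where paralog-induced mismapping would otherwise mimic the
milder log2 shifts. Libraries (e.g. two size-selection windows of the
same digestion) are summed read-wise with `combine_libraries()` before
normalization.

## Normalization, bin filters, log2 ratios

`normalize_counts()` rescales every sample to the mean of the raw
per-sample totals — the scale-free choice that conserves the grand total.
`filter_bins()` then reduces the bin set, sequentially:

| filter | default | removes |
|---|---|---|
| max mean | 150 reads/sample | paralogous or organellar-homology pile-ups |
| min mean | 7 (homdel/dup) or 8 (hetdel) | bins without power to distinguish copy numbers |
| variance/mean | 3 | erratic bins prone to spurious calls |

Bins with zero reads everywhere are set aside before the accounting, so
the filter report starts from "bins with at least one read". Variance is
the sample variance (n − 1). Each removed bin is attributed to the first
filter that rejects it, making the report additive.

`log2_ratio()` computes r = log2((n + 1)/(m + 1)) per sample and
informative bin, where m is the mean normalized count over **all** samples
(including the focal one — with tens of samples the self-contribution is
negligible, and the symmetric definition keeps the matrix
column-exchangeable). The +1 pseudo-counts bound the ratio: a homozygous
deletion in a bin with m ≈ 7 sits at log2(1/8) = −3, which is why the
class boundary for homozygous deletions (−2.5) and the minimum-mean filter
(7) are coupled parameters.

## Segmentation

Profiles are segmented per sample and chromosome over the *ordered
informative-bin sequence* (genomic gaps are ignored; resolution follows
the local bin density). The objective is penalized changepoint detection
under the biweight (bounded) loss:

$$\min \sum_t \min\{(y_t-\theta_{seg(t)})^2,\,K^2\} \;+\; \beta\,\#\text{changepoints}$$

The bounded loss makes single outlier bins powerless: however extreme a
bin is, it contributes at most K² to any segment's cost. The solver
(`segment_profile()`) is an exact functional-pruning dynamic program: the
optimal cost as a function of the current segment level is a piecewise
quadratic in θ, updated in one pass; clipping against the
"open-a-new-segment" constant implements the penalty. Optimal robust
levels per segment are computed exactly by a knot sweep (the loss is
piecewise quadratic in θ with knots at y ± K). Two independent checks
guard the solver: `segment_exhaustive()`, a plain O(n²) dynamic program
over the last changepoint position, and (in the test suite) brute-force
enumeration of all segmentations for n ≤ 12 with an independently coded
cost routine. All three agree to 10⁻⁹ on random instances.

Classification uses the **arithmetic mean** of each segment's log2
ratios; the robust fitted level is reported separately
(`segment_theta`). Ties in optimal cost are broken toward fewer
changepoints.

### Standardization and the shipped calibration

Count noise makes the log2-ratio scale sample-dependent: a sample
sequenced at half depth has visibly noisier ratios after normalization.
The pipeline therefore divides each profile by a robust noise-scale
estimate — the median absolute deviation of lag-1 differences over √2,
which is blind to the piecewise level shifts the segmentation is meant to
find — and applies β and K in noise-sd units (`seg_params(standardize =
TRUE)`, the default). This adapts the penalty to each sample's depth and
automatically de-weights shallow samples, the classic source of spurious
calls in depth-based CNV screens. Degenerate (noiseless or very short)
profiles fall back to scale 1.

The shipped defaults are β = 19, K = 3.8 (σ units). Three constraints fix
the corner of parameter space; the exact values are this package's
calibration, measured on the synthetic populations described below:

1. **No single-bin segments:** K² < 2β (12.96 < 38). One saturated bin can
   never pay for the two changepoints around it.
2. **Three-bin homozygous deletions always split out:** 3K² > 2β
   (43.3 > 38). At default depth a homozygous deletion sits ≈ 5.5 σ below
   baseline — far past the saturation point — so each of its bins
   contributes the full K² of cost reduction. The margin (5.3 σ²) absorbs
   the within-segment spread of deletion bins, whose levels differ with
   the bin's site content.
3. **False segments require ≈ √(2β) ≈ 6 σ excursions** of a local mean,
   rare across a scan of tens of thousands of bins; measured: ≈ 0.1–0.4
   false calls per 24-sample null population, none of them homozygous
   deletions or duplications.

A `relaxed` preset (`pipeline_params("relaxed")`) lowers the penalty to
β = 6 < K² and the support minima to 1–2 bins: single saturated bins can
then seed calls, which maximizes sensitivity for tracking known CNVs at
the cost of many false positives (a zero-count bin arises by chance in a
handful of bins per sample at default depth). This mode exists because
screening applications sometimes value recall over precision; it is not
the discovery default.

The least-squares loss (`loss = "l2"`) is provided for comparison and is
implemented as the same solver with the cutoff placed beyond any
attainable residual, which makes it exactly quadratic.

## From segments to calls

Segments map to at most one type — homozygous deletion if mean < −2.5
(strict), hemizygous deletion if mean ∈ [−2.5, −0.5] (closed), duplication
if mean > 0.2 (strict); means in (−0.5, 0.2] are copy-neutral. The
boundary semantics make classification total and deterministic; a segment
lying exactly at −2.5 is the milder call. Support minima (3 bins for
homozygous deletions, 6 for the others) remove the short segments that
validation shows to be unreliable. Same-type calls whose supporting-bin
index ranges are consecutive — no informative bin of any state between
them — merge into one event with a bin-weighted mean. Spans:

* **minimum span** — from the 3′ end of the first supporting bin to the
  5′ end of the last: an inner bound (empty and flagged for single-bin
  calls). The exported event size is the minimum-span length for all
  three types.
* **maximum span** — from the 5′ start of the nearest informative
  non-supporting bin on the left to the 3′ end of the nearest on the
  right, with chromosome edges substituting at termini: an outer bound.
  "Nearest informative non-supporting bin" is read as the immediate
  flanking bin; the literal "leftmost bin not supporting the deletion"
  would be the chromosome start, which contradicts the span's purpose as
  an outer bracket.

Calls whose maximum span overlaps an exclusion region (naturally
heterogeneous intervals in the population's genetic background, supplied
as BED) by ≥ 1 bp are dropped. Exclusion runs after span computation by
necessity — the rule is defined on the maximum span.

`call_cnvs()` orchestrates the two datasets: homozygous deletions and
duplications from the MQ20 matrix, hemizygous deletions from the MQ35
matrix. No cross-dataset reconciliation is applied by default: a region
may legitimately yield a homozygous-deletion call in one dataset and a
hemizygous call in the other, and downstream validation (e.g. ddPCR) is
the right place to resolve such cases — forcing agreement here would
hide exactly the calls most worth re-checking. `sample_qc()` flags — but
never removes — samples with raw depth below half the population median
or with call counts beyond Q3 + 3·IQR; both symptoms historically mark
samples whose calls are spurious.

## The aCGH companion caller

`call_acgh_homdels()` applies the same segmentation engine to per-probe
aCGH log2 ratios, labels segments with mean < −3 (a hybridization ratio
of 1/8, separating homozygous loss from noise on two-dye arrays), merges
contiguous labeled segments, then drops calls with fewer than 3 probes.
The merge-then-filter order matters — two adjacent 2-probe segments at
different deleted levels jointly survive — and a test pins the order via
such a constructed case. Spans run from the 3′ end of the first supporting
probe to the 5′ start of the last. Hemizygous deletions and duplications
are *not* auto-called from aCGH by default: their milder shifts resist a
single parameterization, and in the validation design they enter as
externally curated truth records (`load_truth_table()`); an opt-in
thresholding mode exists (`call_het_dup = TRUE`) but is excluded from
validation defaults.

## Benchmarking and validation

`match_events()` implements the validation bookkeeping: a call matches a
truth event when sample and type agree and the call's maximum span
overlaps the truth interval by ≥ 1 bp. Unmatched calls are false
positives; unmatched truth events are undetected; one-to-many overlaps are
labeled split/merged links. Conservation holds by construction: every
call and every truth event is counted exactly once. A configurable
reciprocal-overlap mode exists but is off by default (the 1-bp rule is
the benchmark's definition).

`size_agreement()` summarizes one-to-one matched homozygous deletions:
mean minimum- and maximum-span lengths as percentages of the true size,
and the adjusted R² of the ordinary least-squares fit of log10(true size)
on log10(min span) and log10(max span), adjusted as 1 − (1 − R²)(n −
1)/(n − 3) and reported as missing below n = 4.
`detection_by_size()` tabulates detected/undetected truth events by size
class. `count_affected_genes()` counts gene models overlapping each
event's minimum span (conservative; a flag switches to the maximum span),
with multiplicity across lines — the totals measure gene *disruptions*,
not distinct genes.

ddPCR utilities: `ddpcr_copy_number()` is 2 × target concentration /
reference concentration (diploid scaling); `ddpcr_validate()`
operationalizes "approximately twice / approximately half the control"
into bands — duplication validated at mutant:control ratio ∈ [1.6, 2.4],
hemizygous deletion at [0.35, 0.65], ratio ∈ [0.8, 1.25] read as equal
copy number (false positive), mutant < 0.2 copies with a sane control
re-classified as homozygous (the signature of a hemizygous call that was
actually homozygous), and controls outside [1.5, 2.5] copies per
amplified locus inconclusive (multi-locus primer pairs). Band edges are
configurable (`ddpcr_bands()`).

## The synthetic population

`simulate_population()` generates everything the pipeline consumes, from
a single seed:

* informative sites from an inhomogeneous Poisson process — 2 sites/10 kb
  in euchromatic arms, 0.2 in a centered pericentromeric block occupying
  40% of each chromosome (5 × 10 Mb by default), emulating a
  methylation-sensitive enzyme's preference for gene-rich regions;
* two libraries sharing half their sites (the remainder split evenly),
  emulating overlapping size-selection windows;
* expected counts per bin = 12 (depth) × a log-normal per-sample factor
  (sd 0.3, mean 1) × site multiplicity × the planted copy multiplier (0
  for homozygous deletions — the −3-ish ratio then arises purely from the
  pseudo-count, matching the pipeline's arithmetic; 0.5 hemizygous; ≥ 1.5
  duplications). An optional mismapping background for deleted sites is
  off by default;
* negative-binomial counts with dispersion 0.15 (variance μ + 0.15 μ²;
  0 degenerates to Poisson for analytic checks);
* matching aCGH probe profiles (1 probe/kb, Gaussian noise sd 0.3,
  homozygous deletions at level −4) and a truth table with exact
  coordinates. `subsample_depth()` thins counts binomially to emulate
  shallower sequencing runs.

What the simulator does **not** emulate: read-level artifacts (mapping
quality is not simulated — the two MQ regimes of real data collapse onto
one matrix), GC/mappability trends, enzyme-site sequence models,
real heterogeneity regions, and contamination. Passing recovery tests
therefore demonstrates the statistical machinery under a faithful *count*
model, not robustness to alignment pathology.

### Measured operating characteristics, and two instructive interactions

All numbers below are recomputed by `scripts/acceptance.R` and the test
suite; none are assumed. At the default conditions (24 samples, depth 12,
dispersion 0.15), per-bin log2-ratio noise is ≈ 0.6; the variance filter
sits close to the population's var/mean ratio (1 + 0.15·12 ≈ 2.8 vs the
threshold 3), so roughly half the candidate bins are filtered, and —
because a planted event inflates a bin's across-sample variance —
event-carrying bins are filtered *preferentially*. Two consequences:

* **Signal attenuation.** Surviving event bins are biased toward weak
  signal. Multiplier-2 duplications average ≈ +0.5 instead of the naive
  +0.89; single-copy gains (multiplier 1.5) attenuate to ≈ +0.3, which
  straddles the +0.2 class boundary — so single-copy gains have *no
  finite* reliably-detected size here, consistent with duplications being
  the hardest class in practice (they were partly called visually in the
  validation study this mirrors).
* **Combined-library reversal for marginal homozygous deletions.**
  Pooling two libraries doubles depth in shared bins, which doubles the
  event-induced var/mean inflation: event bins are removed *more* often,
  and a 3-bin homozygous deletion at the margin can be lost even though
  total informative bins increase. The combination benefit is real and
  measurable for hemizygous deletions at the detection margin (whose
  variance inflation is negligible); that is where the test asserts it.

Conditioned on adequate informative-bin coverage, recovery at defaults
over 20 seeded replicates: homozygous deletions covering ≥ 3 informative
bins ≈ 100% recovered with zero homozygous-deletion false positives;
hemizygous deletions ≥ 800 kb (≈ ≥ 30 bins) ≈ 100%; multiplier-2
duplications ≥ 50 bins ≈ 85–100%. Minimum reliably detected sizes order
homozygous deletion (≈ 100–200 kb) < hemizygous deletion (≈ 400–800 kb)
< duplication (≈ 1–1.6 Mb at multiplier 2), reproducing the qualitative
hierarchy that motivates using read depth primarily for homozygous
lesions. Matched one-to-one homozygous deletions show minimum spans
averaging ≈ 75% and maximum spans ≈ 120% of true size, a log–log span
model with adjusted R² ≈ 0.92, and true size bracketed by the two spans
in ≥ 95% of cases (bracketing is a homozygous-deletion property; the
fuzzy segment edges of partial-signal types stop short of true
boundaries).

## Numerical and degenerate-input choices

* Sequential filter attribution (first rejecting filter owns the bin)
  keeps the report additive; filtering is idempotent.
* A sample with zero total reads is an error naming the sample (failed
  sequencing must be handled explicitly, not silently rescaled).
* Single-point profiles segment trivially; empty profiles error. The
  exhaustive solver refuses n > 2000 (it is quadratic by design).
* A call supported by one bin has an empty minimum span: width 0,
  flagged `degenerate_span`.
* Reads whose tally coordinate falls outside the chromosome are skipped
  with a warning — the symptom of a grid/reference mismatch.
* Boundary-adjacent saturated outliers can migrate across an existing
  changepoint at zero cost (both sides charge K²); the segment count is
  still invariant. Tests assert exactly that.
* Coordinates are 0-based half-open internally; CSV exports are 1-based
  inclusive and BED exports 0-based half-open, matching each format.

## Problem sizes used by the test suite and acceptance script

The simulation studies use the default population (24 samples, 5 × 10 Mb
chromosomes, ≈ 2,500–3,000 informative bins after filtering): 20
replicates for the recovery/span study, 8 for the detection-size sweep,
and 3–6 for null, depth-monotonicity and library-combination checks.
These sizes give stable percentages (binomial error on 60–80 conditioned
events ≈ a few percent) while keeping a full run in minutes on one CPU.

## Known limitations

* Breakpoints are bounded, not resolved: true edges lie between the
  minimum and maximum spans, and follow-up sequencing is the way to
  refine them.
* Hemizygous deletions and duplications below a few hundred kilobases
  are statistically invisible at GBS bin densities and depths — the
  method's stated trade-off for its cost.
* The variance filter couples to depth and dispersion; at higher depth
  its event-bin bias grows (see above). A depth-aware variance criterion
  would remove this artifact but would depart from the established
  three-filter procedure this package implements.
* Calls in samples flagged by `sample_qc()` deserve visual review of
  their log2-ratio profiles; automation does not replace that step.
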