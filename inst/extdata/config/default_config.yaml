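# Default calling profile: every constant of the GBS CNV pipeline in one
# place.  Homozygous deletions and duplications are called from the MQ>=20
# tally; hemizygous deletions from the MQ>=35 tally.
preset: strict
filters:
  homdel_dup:
    max_mean: 150     # reads/bin: drop suspected paralog/organellar pile-ups
    min_mean: 7       # reads/bin: drop underpowered bins
    varmean_max: 3    # variance-to-mean ratio: drop erratic bins
  hetdel:
    max_mean: 150
    min_mean: 8
    varmean_max: 3
segmentation:
  homdel_dup:
    penalty_beta: 19.0   # cost per changepoint (noise-sd^2 units)
    loss_cutoff_K: 3.8   # biweight saturation (noise-sd units)
    loss: biweight
    standardize: true    # divide profiles by robust noise-scale estimate
  hetdel:
    penalty_beta: 19.0
    loss_cutoff_K: 3.8
    loss: biweight
    standardize: true
thresholds:
  homdel_max: -2.5    # segment mean < -2.5 -> homozygous deletion
  hetdel_min: -2.5    # mean in [-2.5, -0.5] -> hemizygous deletion
  hetdel_max: -0.5
  dup_min: 0.2        # mean > 0.2 -> duplication
  min_bins_homdel: 3
  min_bins_hetdup: 6
exclusions_bed: null   # BED of natural-heterogeneity regions, if any
excluded_samples: []   # e.g. lines failing a contamination screen
output_dir: "."
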