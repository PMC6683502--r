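#' Read a pipeline configuration from YAML
#'
#' A configuration file collects every tunable of the calling pipeline in
#' one auditable place.  Recognized top-level keys (all optional; omitted
#' keys fall back to the preset):
#' `preset` (`strict`/`relaxed`), `filters` (`homdel_dup`, `hetdel`, each
#' with `max_mean`, `min_mean`, `varmean_max`), `segmentation`
#' (`homdel_dup`, `hetdel`, each with `penalty_beta`, `loss_cutoff_K`,
#' `loss`), `thresholds` (`homdel_max`, `hetdel_min`, `hetdel_max`,
#' `dup_min`, `min_bins_homdel`, `min_bins_hetdup`), `exclusions_bed`
#' (path), `excluded_samples` (list), `output_dir`.  The shipped profile at
#' `system.file("extdata/config/default_config.yaml", package = "gbscnv")`
#' encodes the default calling constants.
#'
#' @param path YAML file.
#' @return A list with `params` (a [pipeline_params()]), `exclusions_bed`,
#'   `excluded_samples`, `output_dir`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  preset <- cfg$preset %||% "strict"
  fp <- function(x, min_default) {
    if (is.null(x)) return(filter_params(min_mean = min_default))
    filter_params(max_mean = x$max_mean %||% 150,
                  min_mean = x$min_mean %||% min_default,
                  varmean_max = x$varmean_max %||% 3)
  }
  sp <- function(x) {
    if (is.null(x)) return(NULL)
    seg_params(penalty_beta = x$penalty_beta %||% 19,
               loss_cutoff_K = x$loss_cutoff_K %||% 3.8,
               loss = x$loss %||% "biweight",
               standardize = x$standardize %||% TRUE)
  }
  th <- if (is.null(cfg$thresholds)) NULL else {
    x <- cfg$thresholds
    relaxed <- identical(preset, "relaxed")
    class_thresholds(
      homdel_max = x$homdel_max %||% -2.5,
      hetdel_min = x$hetdel_min %||% -2.5,
      hetdel_max = x$hetdel_max %||% -0.5,
      dup_min = x$dup_min %||% 0.2,
      min_bins_homdel = x$min_bins_homdel %||% (if (relaxed) 1 else 3),
      min_bins_hetdup = x$min_bins_hetdup %||% (if (relaxed) 2 else 6))
  }
  params <- pipeline_params(
    preset = preset,
    filter_homdel_dup = fp(cfg$filters$homdel_dup, 7),
    filter_hetdel = fp(cfg$filters$hetdel, 8),
    seg_homdel_dup = sp(cfg$segmentation$homdel_dup),
    seg_hetdel = sp(cfg$segmentation$hetdel),
    thresholds = th)
  list(params = params,
       exclusions_bed = cfg$exclusions_bed,
       excluded_samples = unlist(cfg$excluded_samples) %||% character(),
       output_dir = cfg$output_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
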