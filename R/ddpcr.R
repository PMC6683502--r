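#' Diploid-scaled copy number from ddPCR concentrations
#'
#' Estimated copies of a target region: the concentration (templates/ul)
#' measured for the target primer pair divided by the concentration of the
#' single-copy reference primer pair in the same sample, times two
#' (diploidy).
#'
#' @param conc_target,conc_ref Non-negative concentrations (vectorized);
#'   every `conc_ref` must be positive.
#' @return Numeric vector of copy numbers.
#' @examples
#' ddpcr_copy_number(1.1, 2.2)  # 1 copy
#' @export
ddpcr_copy_number <- function(conc_target, conc_ref) {
  if (any(!is.finite(conc_ref)) || any(conc_ref <= 0))
    stop("reference concentration must be positive (failed reference assay)")
  if (any(conc_target < 0)) stop("concentrations must be non-negative")
  2 * conc_target / conc_ref
}

#' ddPCR validation bands
#'
#' Operational bands turning "approximately twice / approximately half the
#' control copy number" into verdicts.  `dup` and `hetdel` give the
#' mutant:control copy-ratio intervals that validate those claims;
#' `neutral` is the ratio interval read as equal copy number (false
#' positive); `zero_copies` is the mutant copy number below which the target
#' is treated as absent; `control` is the acceptable control copy-number
#' interval per amplified locus -- controls outside it (multi-locus primer
#' pairs) make the assay inconclusive.
#'
#' @param dup,hetdel,neutral,control Two-element numeric intervals.
#' @param zero_copies Scalar threshold.
#' @export
ddpcr_bands <- function(dup = c(1.6, 2.4), hetdel = c(0.35, 0.65),
                        neutral = c(0.8, 1.25), zero_copies = 0.2,
                        control = c(1.5, 2.5)) {
  structure(list(dup = dup, hetdel = hetdel, neutral = neutral,
                 zero_copies = zero_copies, control = control),
            class = "ddpcr_bands")
}

#' Validate a CNV claim from ddPCR copy numbers
#'
#' Applies the [ddpcr_bands()] rules to mutant and control copy numbers
#' (vectorized).  An assay whose control copy number falls outside the
#' acceptable per-locus interval is `inconclusive`.  A claimed hemizygous
#' deletion with essentially zero mutant copies is `reclassified_homdel`.
#' A mutant:control ratio in the neutral band is a `false_positive`.
#' Otherwise the claim is `validated` when the ratio (or, for homozygous
#' deletions, the mutant copy number) lands in its band, and `inconclusive`
#' when it lands nowhere.
#'
#' @param mutant_copies,control_copies Copy numbers from
#'   [ddpcr_copy_number()].
#' @param claimed_type `"homdel"`, `"hetdel"` or `"dup"` (recycled).
#' @param bands A [ddpcr_bands()].
#' @param multiplicity Number of loci amplified by the primer pair
#'   (default 1); scales the acceptable control interval.
#' @return Character vector of verdicts in
#'   `{validated, false_positive, reclassified_homdel, inconclusive}`.
#' @export
ddpcr_validate <- function(mutant_copies, control_copies, claimed_type,
                           bands = ddpcr_bands(), multiplicity = 1) {
  n <- max(length(mutant_copies), length(control_copies),
           length(claimed_type))
  mutant <- rep_len(mutant_copies, n)
  control <- rep_len(control_copies, n)
  claim <- rep_len(claimed_type, n)
  mult <- rep_len(multiplicity, n)
  if (!all(claim %in% c("homdel", "hetdel", "dup")))
    stop("claimed_type must be homdel, hetdel or dup")
  inb <- function(x, b) x >= b[1] & x <= b[2]
  verdict <- character(n)
  ratio <- ifelse(control > 0, mutant / control, NA_real_)
  for (i in seq_len(n)) {
    if (!inb(control[i] / mult[i], bands$control)) {
      verdict[i] <- "inconclusive"
    } else if (claim[i] == "hetdel" && mutant[i] < bands$zero_copies) {
      verdict[i] <- "reclassified_homdel"
    } else if (claim[i] == "homdel") {
      verdict[i] <- if (mutant[i] < bands$zero_copies) "validated"
        else if (inb(ratio[i], bands$neutral)) "false_positive"
        else "inconclusive"
    } else if (inb(ratio[i], bands[[claim[i]]])) {
      verdict[i] <- "validated"
    } else if (inb(ratio[i], bands$neutral)) {
      verdict[i] <- "false_positive"
    } else {
      verdict[i] <- "inconclusive"
    }
  }
  verdict
}

#' Load a ddPCR assay table
#'
#' Reads the assay CSV schema with per-assay mutant and control
#' concentrations (`ID`, `CNV_type`, `primer_pair`, `mutant_conc`,
#' `mutant_ref`, `control_conc`, `control_ref`, ...), computes copy numbers
#' and the mutant:control ratio.
#'
#' @param path CSV file path.
#' @return The table with added columns `mutant_n`, `control_n`, `ratio`.
#' @export
load_ddpcr_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("mutant_conc", "mutant_ref", "control_conc", "control_ref")
  if (!all(need %in% names(df)))
    stop("ddPCR table must have columns ", paste(need, collapse = ", "))
  df$mutant_n <- ddpcr_copy_number(df$mutant_conc, df$mutant_ref)
  df$control_n <- ddpcr_copy_number(df$control_conc, df$control_ref)
  df$ratio <- df$mutant_n / df$control_n
  df
}
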