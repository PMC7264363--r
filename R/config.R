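# Pipeline configuration.

#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the site-calling pipeline. Defaults
#' mirror the processing used for a LogProb-scored search-engine export:
#' score filter at 2 (corresponding to peptide FDR <= 1% in the original
#' search; FDR itself is not recomputed here), absolute mass-match tolerance
#' 0.01 Da (wide enough to absorb the two printed precisions of the label
#' masses, e.g. 145.0198 vs +145.020), and a minimum of three supporting
#' observations per site and condition.
#'
#' @param min_logprob Minimum identification score (inclusive).
#' @param mass_tolerance Absolute tolerance (Da) when matching a reported mass
#'   shift to a label mass.
#' @param min_support Minimum observations per (site, condition) for the site
#'   to be called in that condition.
#' @param label_masses Mass shifts (Da) accepted as label evidence.
#' @param control_min_support Control-sample support at or above which a site
#'   is subtracted.
#' @param block_before_proline Apply the Keil rule (no cleavage before
#'   proline) in digestion models.
#' @param support_unit Count support as observation rows (`"observations"`,
#'   PSM-level) or distinct peptide sequences (`"distinct_peptides"`).
#' @param mature_nterm Treat a position-0 label on a peptide starting at
#'   residue 2 of a Met-initiated protein as a protein N-terminal label
#'   (initiator-methionine removal).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_logprob = 2,
                            mass_tolerance = 0.01,
                            min_support = 3L,
                            label_masses = label_mods()$delta_mass,
                            control_min_support = 3L,
                            block_before_proline = TRUE,
                            support_unit = c("observations", "distinct_peptides"),
                            mature_nterm = TRUE) {
  support_unit <- match.arg(support_unit)
  stopifnot(min_support >= 1L, mass_tolerance > 0, control_min_support >= 1L,
            length(label_masses) >= 1L)
  structure(list(min_logprob = min_logprob,
                 mass_tolerance = mass_tolerance,
                 min_support = as.integer(min_support),
                 label_masses = label_masses,
                 control_min_support = as.integer(control_min_support),
                 block_before_proline = isTRUE(block_before_proline),
                 support_unit = support_unit,
                 mature_nterm = isTRUE(mature_nterm)),
            class = "pipeline_config")
}
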