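# Monoisotopic mass arithmetic for the label chemistry.
#
# Standard monoisotopic atomic masses (IUPAC/CODATA, >= 6 decimals) are embedded
# as constants so that mass computations are self-contained and testable.

.MONO_MASS <- c(
  C = 12.000000000,
  H = 1.007825032,
  N = 14.003074005,
  O = 15.994914620,
  S = 31.972070690
)

#' Monoisotopic mass of an elemental composition
#'
#' Computes the monoisotopic mass of a neutral elemental composition written in
#' Hill-like notation over the elements C, H, N, O and S (e.g. `"C3H4OS"`).
#' An omitted count means one atom; the empty string has mass zero.
#'
#' @param formula Character scalar, e.g. `"C5H7NO2S"`.
#' @return Mass in Da (numeric scalar).
#' @examples
#' monoisotopic_mass("C3H4OS")   # thioacyl label remnant, 87.9983 Da
#' monoisotopic_mass("C5H7NO2S") # alkylated (CAMthiopropanoyl) remnant
#' @export
monoisotopic_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (formula == "") return(0)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) {
    stop("malformed formula: '", formula, "'")
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  elems <- sub("[0-9]*$", "", parts)
  counts <- as.integer(sub("^[A-Z][a-z]?", "", paste0(parts, "")))
  counts[is.na(counts)] <- 1L
  unknown <- setdiff(elems, names(.MONO_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(.MONO_MASS[elems] * counts)
}

#' Label modification definitions
#'
#' The two covalent remnants that a cleavable, amine-reactive surface
#' biotinylation reagent (Sulfo-NHS-SS-biotin) leaves on extracellular primary
#' amino groups after reductive elution: the non-alkylated thioacyl form
#' (+87.9983 Da) and the iodoacetamide-alkylated CAMthiopropanoyl form
#' (+145.0198 Da). Both can sit on lysine side chains, protein N-termini and
#' peptide N-termini (the latter created by pre-digestion of the cell surface).
#' Masses are computed from the elemental compositions of the remnants.
#'
#' @return A data.frame with columns `name`, `formula`, `delta_mass` and
#'   `contexts` (comma-separated allowed residue contexts).
#' @export
label_mods <- function() {
  data.frame(
    name = c("thioacyl", "CAMthiopropanoyl"),
    formula = c("C3H4OS", "C5H7NO2S"),
    delta_mass = c(monoisotopic_mass("C3H4OS"), monoisotopic_mass("C5H7NO2S")),
    contexts = "protein_nterm,peptide_nterm,lysine_sidechain",
    stringsAsFactors = FALSE
  )
}

#' Deamidation mass shift
#'
#' The +0.984 Da shift of spontaneous or PNGaseF-induced asparagine
#' deamidation (N -> D), computed as the O - N - H mass difference. This shift
#' is a confounder of label evidence and must never be counted as a label.
#'
#' @return Mass shift in Da (numeric scalar).
#' @export
deamidation_mass <- function() {
  unname(.MONO_MASS["O"] - .MONO_MASS["N"] - .MONO_MASS["H"])
}
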