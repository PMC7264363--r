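# Protease digestion models.
#
# Trypsin cleaves C-terminal of K and R; chymotrypsin (high-specificity rule)
# C-terminal of F, Y, W, M and L. Both default to the Keil rule (no cleavage
# before proline). A labelled lysine side chain is never a tryptic cleavage
# site: callers pass such positions as `blocked`.

#' Protease cleavage rule
#'
#' @param name `"trypsin"` or `"chymotrypsin"`.
#' @param block_before_proline Apply the Keil rule.
#' @return A list of class `enzyme_rule` with elements `name`, `cleave_after`
#'   (P1 residue set) and `block_before_proline`.
#' @export
enzyme_rule <- function(name = c("trypsin", "chymotrypsin"),
                        block_before_proline = TRUE) {
  name <- match.arg(name)
  cleave_after <- switch(name,
                         trypsin = c("K", "R"),
                         chymotrypsin = c("F", "Y", "W", "M", "L"))
  structure(list(name = name, cleave_after = cleave_after,
                 block_before_proline = isTRUE(block_before_proline)),
            class = "enzyme_rule")
}

#' Eligible cleavage sites of a sequence
#'
#' Position `p` is a cut (cleavage happens after residue `p`) iff residue `p`
#' is in the rule's P1 set, `p` is not the last residue, `p` is not blocked
#' (e.g. a labelled lysine), and — under the Keil rule — residue `p + 1` is
#' not proline.
#'
#' @param sequence Amino-acid string.
#' @param rule An [enzyme_rule()].
#' @param blocked Integer vector of 1-based positions that must not be cut.
#' @return Sorted integer vector of cut positions.
#' @export
cleavage_sites <- function(sequence, rule, blocked = integer(0)) {
  stopifnot(nzchar(sequence))
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  p <- which(aa %in% rule$cleave_after)
  p <- p[p < n]
  if (rule$block_before_proline) p <- p[aa[p + 1L] != "P"]
  sort(setdiff(p, as.integer(blocked)))
}

fragments_from_cuts <- function(sequence, cuts) {
  n <- nchar(sequence)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  data.frame(start = starts, end = ends,
             sequence = substring(sequence, starts, ends),
             stringsAsFactors = FALSE)
}

#' Complete digestion with missed cleavages
#'
#' With `max_missed = 0` the fragments partition the sequence in order; with
#' `m > 0` every concatenation of up to `m + 1` adjacent fragments is emitted
#' as well. Labelled lysines, passed via `blocked`, are never cleaved
#' regardless of the missed-cleavage cap.
#'
#' @inheritParams cleavage_sites
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @return A data.frame of fragments (`start`, `end`, `sequence`, `missed`).
#' @export
digest_full <- function(sequence, rule, blocked = integer(0), max_missed = 0L) {
  stopifnot(max_missed >= 0L)
  cuts <- cleavage_sites(sequence, rule, blocked)
  base <- fragments_from_cuts(sequence, cuts)
  base$missed <- 0L
  if (max_missed == 0L || nrow(base) == 1L) return(base)
  out <- list(base)
  for (m in seq_len(min(max_missed, nrow(base) - 1L))) {
    i <- seq_len(nrow(base) - m)
    out[[m + 1L]] <- data.frame(
      start = base$start[i], end = base$end[i + m],
      sequence = substring(sequence, base$start[i], base$end[i + m]),
      missed = m, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Partial (probabilistic) digestion
#'
#' Models mild proteolysis: each eligible cleavage site is cut independently
#' with probability `p_cleave` (a Bernoulli per-site model; the probability
#' maps monotonically to digestion time). Output fragments partition the
#' sequence. Reproducible given `seed`.
#'
#' @inheritParams cleavage_sites
#' @param p_cleave Per-site cut probability in [0, 1].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A data.frame of fragments (`start`, `end`, `sequence`).
#' @export
digest_partial <- function(sequence, rule, p_cleave, blocked = integer(0),
                           seed = NULL) {
  stopifnot(p_cleave >= 0, p_cleave <= 1)
  sites <- cleavage_sites(sequence, rule, blocked)
  draw <- function() sites[stats::runif(length(sites)) < p_cleave]
  cuts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  fragments_from_cuts(sequence, cuts)
}
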