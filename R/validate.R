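# Topology validation of called sites and export of extracellular
# constraints.

#' Classify a called site against reference topology
#'
#' `O` residues validate as Extracellular; `I` and `M` residues as
#' Intracellular ("not an extracellular position" — membrane residues are
#' reported in a diagnostic column by [summarize_validation()] so
#' membrane-adjacent calls stay visible); `U` (or a protein without topology)
#' as Unknown.
#'
#' @param accession,position Site coordinates (vectors of equal length).
#' @param prot A `proteome` with topology attached.
#' @return Character vector over `{"Extracellular", "Intracellular",
#'   "Unknown"}`.
#' @export
classify_site <- function(accession, position, prot) {
  i <- match(accession, prot$accession)
  if (anyNA(i)) {
    stop("unknown accession(s): ",
         paste(unique(accession[is.na(i)]), collapse = ", "))
  }
  if (any(position < 1L | position > nchar(prot$sequence[i]))) {
    stop("site position out of protein range")
  }
  topo <- prot$topology[i]
  lab <- ifelse(is.na(topo), "U",
                substr(topo, position, position))
  unname(c(O = "Extracellular", I = "Intracellular", M = "Intracellular",
           U = "Unknown")[lab])
}

#' Validation summary of called sites
#'
#' Per condition, counts called sites by reference class (Extracellular /
#' Unknown / Intracellular, plus a diagnostic count of membrane-residue
#' calls within Intracellular), and computes the accuracy over the merged
#' unique site set: Extracellular / (Extracellular + Intracellular) among
#' sites with a known class, reported as `NA` when no known-class site
#' exists. The known fraction (non-Unknown / all) is also emitted.
#'
#' @param sites Aggregated site table.
#' @param called Named list from [called_sets()].
#' @param prot A `proteome` with topology attached.
#' @return A list of class `validation_summary`: `by_condition` (data.frame),
#'   `accuracy` (fraction), `accuracy_pct`, `known_fraction`,
#'   `merged_counts`, `n_merged`.
#' @export
summarize_validation <- function(sites, called, prot) {
  key <- site_key(sites$accession, sites$position)
  cls <- classify_site(sites$accession, sites$position, prot)
  i <- match(sites$accession, prot$accession)
  is_m <- !is.na(prot$topology[i]) &
    substr(prot$topology[i], sites$position, sites$position) == "M"
  by_cond <- do.call(rbind, lapply(names(called), function(cid) {
    sel <- key %in% called[[cid]]
    data.frame(condition_id = cid,
               Extracellular = sum(cls[sel] == "Extracellular"),
               Unknown = sum(cls[sel] == "Unknown"),
               Intracellular = sum(cls[sel] == "Intracellular"),
               membrane_residue = sum(is_m[sel]),
               n_called = sum(sel), stringsAsFactors = FALSE)
  }))
  merged <- key %in% unique(unlist(called))
  counts <- c(Extracellular = sum(cls[merged] == "Extracellular"),
              Unknown = sum(cls[merged] == "Unknown"),
              Intracellular = sum(cls[merged] == "Intracellular"))
  known <- counts["Extracellular"] + counts["Intracellular"]
  acc <- if (known > 0) unname(counts["Extracellular"] / known) else NA_real_
  structure(list(by_condition = by_cond,
                 merged_counts = counts,
                 n_merged = sum(merged),
                 accuracy = acc,
                 accuracy_pct = if (is.na(acc)) NA_real_ else 100 * acc,
                 known_fraction = if (sum(merged)) unname(known / sum(merged))
                                  else NA_real_),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("Validation against reference topology\n")
  print(x$by_condition, row.names = FALSE)
  cat(sprintf("merged unique sites: %d (known class: %.1f%%)\n",
              x$n_merged, 100 * x$known_fraction))
  if (is.na(x$accuracy)) {
    cat("accuracy: N/A (no site with known class)\n")
  } else {
    cat(sprintf("accuracy: %.1f%% (%d/%d known-class sites extracellular)\n",
                x$accuracy_pct, x$merged_counts[["Extracellular"]],
                x$merged_counts[["Extracellular"]] +
                  x$merged_counts[["Intracellular"]]))
  }
  invisible(x)
}

#' Pre-digestion mechanism statistics
#'
#' Quantifies how much of the evidence exists only because of surface
#' pre-digestion: (a) the fraction of N-terminally labelled peptides
#' (distinct sequences carrying a position-0 label) detected only in
#' pre-digested conditions, and (b) the fraction of called sites unique to
#' pre-digested conditions. With ground truth available, digest-only sites
#' are cross-tabulated by generation cause.
#'
#' @param evidence Valid site evidence (labelled samples).
#' @param called Named list from [called_sets()].
#' @param predigested Character vector of pre-digested condition ids.
#' @param truth Optional truth data.frame from [simulate_experiment()].
#' @return A list: `nterm_digest_only_fraction`, `site_digest_only_fraction`,
#'   `digest_only_causes` (or `NULL`).
#' @export
mechanism_stats <- function(evidence, called, predigested, truth = NULL) {
  if (!length(predigested)) {
    warning("no pre-digested conditions supplied")
    return(list(nterm_digest_only_fraction = 0,
                site_digest_only_fraction = 0,
                digest_only_causes = NULL))
  }
  ev <- evidence[evidence$valid &
                   evidence$context %in% c("protein_nterm", "peptide_nterm"), ]
  frac_a <- if (nrow(ev)) {
    conds <- split(ev$condition_id, ev$peptide)
    mean(vapply(conds, function(x) all(x %in% predigested), logical(1)))
  } else 0
  all_called <- unique(unlist(called))
  dig <- unique(unlist(called[intersect(predigested, names(called))]))
  ctrl <- unique(unlist(called[setdiff(names(called), predigested)]))
  dig_only <- setdiff(dig, ctrl)
  frac_b <- if (length(all_called)) length(dig_only) / length(all_called)
            else 0
  causes <- NULL
  if (!is.null(truth) && length(dig_only)) {
    tk <- site_key(truth$accession, truth$position)
    causes <- table(truth$cause[tk %in% dig_only & !duplicated(tk)])
  }
  list(nterm_digest_only_fraction = frac_a,
       site_digest_only_fraction = frac_b,
       digest_only_causes = causes)
}

#' Write extracellular constraints
#'
#' One line per called site — `accession<TAB>position<TAB>O` — sorted by
#' accession then position: a constraint list consumable by consensus
#' topology predictors. This evidence type only ever supports extracellular
#' ("O") constraints.
#'
#' @param sites Aggregated site table.
#' @param called Named list from [called_sets()] (the merged unique set is
#'   exported).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_constraints <- function(sites, called, path) {
  key <- site_key(sites$accession, sites$position)
  sel <- sites[key %in% unique(unlist(called)), , drop = FALSE]
  sel <- sel[order(sel$accession, sel$position), , drop = FALSE]
  df <- data.frame(accession = sel$accession, position = sel$position,
                   label = rep("O", nrow(sel)), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a constraint file
#'
#' @param path File written by [write_constraints()].
#' @return A data.frame with `accession`, `position`, `label`.
#' @export
read_constraints <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(accession = character(0), position = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("accession", "position", "label"))
}
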