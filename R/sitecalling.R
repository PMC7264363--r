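# Observation filtering, minimum-support site aggregation, control
# subtraction and condition-set comparison.

has_label_mod <- function(mods, config) {
  vapply(strsplit(mods, "[;:]"), function(v) {
    if (!length(v) || identical(v, "")) return(FALSE)
    d <- as.numeric(v[seq(2L, length(v), 2L)])
    any(vapply(d, function(x) {
      any(abs(config$label_masses - x) <= config$mass_tolerance)
    }, logical(1)))
  }, logical(1))
}

#' Filter observations by score and label mass
#'
#' Keeps rows whose score is at least `min_logprob` (inclusive boundary) and
#' which carry at least one modification within `mass_tolerance` of a label
#' mass. Rows whose only modification is deamidation (+0.984 Da) or any other
#' non-label shift are removed: such shifts are never label evidence. Removal
#' counts by reason are attached as the `"removed"` attribute.
#'
#' @param obs Observation data.frame.
#' @param config A [pipeline_config()].
#' @return The filtered data.frame with attribute `removed` =
#'   `c(score_below, no_label_mod)`.
#' @export
filter_observations <- function(obs, config = pipeline_config()) {
  score_ok <- obs$score >= config$min_logprob
  label_ok <- has_label_mod(obs$mods, config)
  keep <- score_ok & label_ok
  out <- obs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(score_below = sum(!score_ok),
                            no_label_mod = sum(score_ok & !label_ok))
  out
}

site_key <- function(accession, position) {
  if (!length(accession)) return(character(0))
  paste0(accession, ":", position)
}

#' Aggregate site evidence into labelled sites
#'
#' Groups valid evidence rows by (accession, position) and counts support per
#' condition — as observation rows (PSM-level, the default) or as distinct
#' peptide sequences, per `config$support_unit`. A site's context can differ
#' across observations (e.g. lysine side chain in one peptide, peptide
#' N-terminus in another); all observed contexts are recorded at the one
#' position.
#'
#' @param evidence Site-evidence data.frame from [map_observations()]
#'   (labelled samples; invalid rows are ignored).
#' @param config A [pipeline_config()].
#' @return A data.frame with one row per site: `accession`, `position`,
#'   `residue`, `contexts` (comma-joined), `ambiguous_only`, plus one
#'   `support.<condition_id>` column per condition.
#' @export
aggregate_sites <- function(evidence, config = pipeline_config()) {
  ev <- evidence[evidence$valid, , drop = FALSE]
  if (!nrow(ev)) {
    return(data.frame(accession = character(0), position = integer(0),
                      residue = character(0), contexts = character(0),
                      ambiguous_only = logical(0), stringsAsFactors = FALSE))
  }
  key <- site_key(ev$accession, ev$position)
  conds <- sort(unique(ev$condition_id))
  ukey <- !duplicated(key)
  sites <- data.frame(accession = ev$accession[ukey],
                      position = ev$position[ukey],
                      residue = ev$residue[ukey],
                      stringsAsFactors = FALSE)
  rownames(sites) <- key[ukey]
  sites$contexts <- vapply(split(ev$context, key), function(x) {
    paste(sort(unique(x)), collapse = ",")
  }, "")[rownames(sites)]
  sites$ambiguous_only <- vapply(split(ev$ambiguous, key), all,
                                 logical(1))[rownames(sites)]
  for (cid in conds) {
    sel <- ev$condition_id == cid
    cnt <- if (config$support_unit == "distinct_peptides") {
      tapply(ev$peptide[sel], key[sel], function(p) length(unique(p)))
    } else {
      table(key[sel])
    }
    col <- paste0("support.", cid)
    sites[[col]] <- 0L
    sites[names(cnt), col] <- as.integer(cnt)
  }
  sites <- sites[order(sites$accession, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Called-site sets per condition
#'
#' A site is called in a condition iff its support there reaches
#' `min_support`.
#'
#' @param sites Aggregated site table from [aggregate_sites()].
#' @param min_support Support threshold.
#' @return Named list (by condition) of `"accession:position"` keys.
#' @export
called_sets <- function(sites, min_support = 3L) {
  cols <- grep("^support\\.", names(sites), value = TRUE)
  out <- lapply(cols, function(cl) {
    site_key(sites$accession, sites$position)[sites[[cl]] >= min_support]
  })
  names(out) <- sub("^support\\.", "", cols)
  out
}

#' Subtract control-supported sites
#'
#' Removes sites whose support in control (unlabelled) samples reaches
#' `control_min_support`; with sparse control evidence (the usual case) the
#' output equals the input. Removed keys are attached as attribute
#' `"control_removed"`.
#'
#' @param sites Aggregated site table (labelled samples).
#' @param control_evidence Site evidence from unlabelled control samples (may
#'   be empty or `NULL`).
#' @param config A [pipeline_config()].
#' @return The site table without control-supported sites.
#' @export
subtract_control <- function(sites, control_evidence,
                             config = pipeline_config()) {
  removed <- character(0)
  if (!is.null(control_evidence) && nrow(control_evidence)) {
    cev <- control_evidence[control_evidence$valid, , drop = FALSE]
    if (nrow(cev)) {
      cnt <- table(site_key(cev$accession, cev$position))
      removed <- names(cnt)[cnt >= config$control_min_support]
    }
  }
  keep <- !(site_key(sites$accession, sites$position) %in% removed)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "control_removed") <- removed
  out
}

#' Compare called-site sets across conditions
#'
#' For each enzyme series, the merged digest set is the union of that
#' enzyme's pre-digested conditions; it is partitioned against the series'
#' non-pre-digested control (NPC/NPT) into control-only ("lost to
#' pre-digestion"), shared, and digest-only ("gained by pre-digestion")
#' sites.
#'
#' @param called Named list of called-site key sets (from [called_sets()]).
#' @param series Named list, one entry per enzyme series:
#'   `list(control = <condition_id>, digest = <condition_ids>)`.
#' @return A list of class `condition_comparison`; per series: the three
#'   partition counts, the member site keys, and the merged digest set.
#' @export
compare_conditions <- function(called, series) {
  out <- lapply(names(series), function(sn) {
    s <- series[[sn]]
    ctrl <- if (s$control %in% names(called)) called[[s$control]] else
      character(0)
    dig <- sort(unique(unlist(called[intersect(s$digest, names(called))])))
    both <- intersect(ctrl, dig)
    res <- list(control_only = setdiff(ctrl, dig),
                shared = both,
                digest_only = setdiff(dig, ctrl),
                merged_digest = dig)
    res$counts <- c(control_only = length(res$control_only),
                    shared = length(res$shared),
                    digest_only = length(res$digest_only),
                    union = length(union(ctrl, dig)))
    res
  })
  names(out) <- names(series)
  structure(out, class = "condition_comparison")
}

#' Per-condition labelled-protein and position counts
#'
#' Counts, per condition, the transmembrane proteins (topology with >= 1 `M`
#' residue) carrying at least one called site and their called positions;
#' proteins without membrane residues are tallied separately.
#'
#' @param sites Aggregated site table.
#' @param called Named list from [called_sets()].
#' @param prot A `proteome` with topology attached.
#' @return A data.frame: `condition_id`, `tmp_proteins`, `tmp_positions`,
#'   `nontmp_proteins`, `nontmp_positions`.
#' @export
summarize_counts <- function(sites, called, prot) {
  tmp_acc <- prot$accession[is_tmp(prot)]
  key <- site_key(sites$accession, sites$position)
  do.call(rbind, lapply(names(called), function(cid) {
    sel <- sites[key %in% called[[cid]], , drop = FALSE]
    on_tmp <- sel$accession %in% tmp_acc
    data.frame(condition_id = cid,
               tmp_proteins = length(unique(sel$accession[on_tmp])),
               tmp_positions = sum(on_tmp),
               nontmp_proteins = length(unique(sel$accession[!on_tmp])),
               nontmp_positions = sum(!on_tmp),
               stringsAsFactors = FALSE)
  }))
}

#' Dataset-level summary statistics
#'
#' Aggregate descriptive statistics of a filtered observation table: labelled
#' peptide counts per enzyme series, the fraction of labels observed in the
#' alkylated (+145.0198 Da) form, and the fraction of all identified peptides
#' that are either labelled or cysteine-containing (piggyback).
#'
#' @param obs Observation data.frame (pre-filter, labelled samples).
#' @param config A [pipeline_config()].
#' @return A list: `n_labelled_by_enzyme`, `alkylated_fraction`,
#'   `labelled_or_cys_fraction`, `n_observations`.
#' @export
dataset_summary <- function(obs, config = pipeline_config()) {
  lab <- has_label_mod(obs$mods, config)
  cam <- label_mods()
  cam_mass <- cam$delta_mass[cam$name == "CAMthiopropanoyl"]
  is_cam <- vapply(strsplit(obs$mods, "[;:]"), function(v) {
    if (!length(v) || identical(v, "")) return(FALSE)
    d <- as.numeric(v[seq(2L, length(v), 2L)])
    any(abs(d - cam_mass) <= config$mass_tolerance)
  }, logical(1))
  has_c <- grepl("C", obs$peptide, fixed = TRUE)
  list(
    n_labelled_by_enzyme = table(obs$enzyme[lab]),
    alkylated_fraction = if (any(lab)) mean(is_cam[lab]) else NA_real_,
    labelled_or_cys_fraction = if (nrow(obs)) mean(lab | has_c) else NA_real_,
    n_observations = nrow(obs))
}
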