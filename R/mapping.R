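# Peptide-to-proteome mapping and modification-site localization.
#
# Peptides are located by exact substring search across all proteins (a
# deterministic, exhaustively testable replacement for short-peptide BLAST
# lookup). Peptide-coordinate modifications are then converted to protein
# coordinates and classified by residue context.

#' Locate peptides in a proteome by exact substring search
#'
#' Finds every exact occurrence of each peptide across all proteins. A match
#' is flagged ambiguous when the peptide occurs at more than one locus in the
#' whole proteome. Peptides shorter than 5 residues are searched but trigger
#' a warning (they map promiscuously).
#'
#' @param peptides Character vector of peptide sequences (deduplicated
#'   internally).
#' @param prot A `proteome` data.frame.
#' @return A data.frame with columns `peptide`, `accession`, `start`, `end`,
#'   `ambiguous`. Peptides without a match are absent.
#' @export
locate_peptides <- function(peptides, prot) {
  peptides <- unique(peptides)
  short <- peptides[nchar(peptides) < 5L]
  if (length(short)) {
    warning("peptide(s) shorter than 5 residues searched: ",
            paste(utils::head(short, 5L), collapse = ", "),
            if (length(short) > 5L) ", ...")
  }
  if (!nrow(prot) || !length(peptides)) {
    return(data.frame(peptide = character(0), accession = character(0),
                      start = integer(0), end = integer(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE))
  }
  # one concatenated subject with a separator that is not an amino acid
  big <- paste(prot$sequence, collapse = "#")
  offset <- c(0L, cumsum(nchar(prot$sequence) + 1L))
  hits <- lapply(peptides, function(p) {
    g <- gregexpr(p, big, fixed = TRUE)[[1]]
    if (g[1] == -1L) return(NULL)
    idx <- findInterval(as.integer(g), offset[-1] + 1L) + 1L
    data.frame(peptide = p, accession = prot$accession[idx],
               start = as.integer(g) - offset[idx], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(peptide = character(0), accession = character(0),
                      start = integer(0), end = integer(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE))
  }
  out$end <- out$start + nchar(out$peptide) - 1L
  nhit <- table(out$peptide)
  out$ambiguous <- as.vector(nhit[out$peptide]) > 1L
  rownames(out) <- NULL
  out
}

#' Locate a single peptide
#'
#' @param peptide Peptide sequence.
#' @param prot A `proteome` data.frame.
#' @return See [locate_peptides()]; empty data.frame when unmatched.
#' @export
locate_peptide <- function(peptide, prot) {
  locate_peptides(peptide, prot)
}

#' Localize label modifications of a matched peptide
#'
#' For every reported modification whose mass shift lies within
#' `config$mass_tolerance` of a label mass, converts the peptide-coordinate
#' position to a protein coordinate and assigns a residue context:
#' \itemize{
#'   \item position 0 (peptide N-terminal amine): `protein_nterm` when the
#'     match starts at residue 1 — or at residue 2 of a Met-initiated protein
#'     when `config$mature_nterm` is set (initiator-methionine removal) —
#'     otherwise `peptide_nterm`; the site position is the match start;
#'   \item position `p > 0` on a lysine: `lysine_sidechain` at protein
#'     position `start + p - 1`;
#'   \item position `p > 0` on any other residue: recorded as invalid
#'     evidence with a reason (never silently dropped).
#' }
#' Non-label mass shifts (e.g. +0.984 Da deamidation) are ignored: they are
#' not label evidence.
#'
#' @param match One row of [locate_peptides()] output.
#' @param mods Parsed modifications (data.frame `pos`, `delta`, from
#'   [parse_mods()]).
#' @param prot A `proteome` data.frame.
#' @param config A [pipeline_config()].
#' @return A data.frame with columns `accession`, `position`, `residue`,
#'   `context`, `mod`, `valid`, `reason`.
#' @export
localize_modifications <- function(match, mods, prot, config = pipeline_config()) {
  defs <- label_mods()
  seqs <- prot$sequence[match(match$accession, prot$accession)]
  out <- list()
  for (j in seq_len(nrow(mods))) {
    d <- abs(defs$delta_mass - mods$delta[j])
    if (min(d) > config$mass_tolerance) next  # not a label mass
    mod_name <- defs$name[which.min(d)]
    p <- mods$pos[j]
    if (p == 0L) {
      is_protein_nterm <- match$start == 1L ||
        (config$mature_nterm && match$start == 2L &&
           substr(seqs, 1L, 1L) == "M")
      out[[length(out) + 1L]] <- data.frame(
        accession = match$accession, position = match$start,
        residue = substr(seqs, match$start, match$start),
        context = if (is_protein_nterm) "protein_nterm" else "peptide_nterm",
        mod = mod_name, valid = TRUE, reason = "", stringsAsFactors = FALSE)
    } else {
      pos <- match$start + p - 1L
      res <- substr(seqs, pos, pos)
      ok <- res == "K"
      out[[length(out) + 1L]] <- data.frame(
        accession = match$accession, position = pos, residue = res,
        context = if (ok) "lysine_sidechain" else "invalid",
        mod = mod_name, valid = ok,
        reason = if (ok) "" else "label mass on internal non-K residue",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(accession = character(0), position = integer(0),
                      residue = character(0), context = character(0),
                      mod = character(0), valid = logical(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Flag piggyback peptides
#'
#' A piggyback peptide contains cysteine and carries no label-mass
#' modification: it co-purifies on the affinity column through a disulphide
#' bond to a labelled peptide rather than through a label of its own.
#'
#' @param peptide Peptide sequence(s).
#' @param mods Mods string(s) (`"pos:delta;..."`).
#' @param config A [pipeline_config()].
#' @return Logical vector.
#' @export
flag_piggyback <- function(peptide, mods, config = pipeline_config()) {
  has_c <- grepl("C", peptide, fixed = TRUE)
  has_label <- vapply(mods, function(m) {
    pm <- parse_mods(m)
    any(vapply(pm$delta, function(d) {
      any(abs(config$label_masses - d) <= config$mass_tolerance)
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  has_c & !has_label
}

#' Map observations to site evidence
#'
#' Locates every observed peptide in the proteome and localizes its label
#' modifications, producing one site-evidence row per (match, label mod).
#' Ambiguous (multi-locus) peptides contribute evidence to every matched
#' protein and carry `ambiguous = TRUE`; unmatched peptides and invalid
#' localizations are retained with `valid = FALSE` and a reason.
#'
#' @param obs Observation data.frame (see [observation_table()]).
#' @param prot A `proteome` data.frame.
#' @param config A [pipeline_config()].
#' @return A site-evidence data.frame: `accession`, `position`, `residue`,
#'   `context`, `mod`, `sample_id`, `condition_id`, `labelled`, `peptide`,
#'   `score`, `ambiguous`, `valid`, `reason`.
#' @export
map_observations <- function(obs, prot, config = pipeline_config()) {
  empty <- data.frame(accession = character(0), position = integer(0),
                      residue = character(0), context = character(0),
                      mod = character(0), sample_id = character(0),
                      condition_id = character(0), labelled = logical(0),
                      peptide = character(0), score = numeric(0),
                      ambiguous = logical(0), valid = logical(0),
                      reason = character(0), stringsAsFactors = FALSE)
  if (!nrow(obs)) return(empty)
  loc <- locate_peptides(obs$peptide, prot)

  # evidence is a pure function of (peptide, mods); map unique pairs once
  key <- paste(obs$peptide, obs$mods, sep = "\r")
  ukey <- unique(key)
  upep <- sub("\r.*$", "", ukey)
  umods <- sub("^[^\r]*\r", "", ukey)
  loc_idx <- split(seq_len(nrow(loc)), loc$peptide)
  tmpl <- lapply(seq_along(ukey), function(u) {
    m <- loc[loc_idx[[upep[u]]], , drop = FALSE]
    if (!nrow(m)) {
      return(data.frame(
        accession = NA_character_, position = NA_integer_,
        residue = NA_character_, context = "unmapped", mod = NA_character_,
        ambiguous = FALSE, valid = FALSE,
        reason = "peptide not found in proteome", stringsAsFactors = FALSE))
    }
    pm <- parse_mods(umods[u])
    ev <- do.call(rbind, lapply(seq_len(nrow(m)), function(k) {
      e <- localize_modifications(m[k, ], pm, prot, config)
      e$ambiguous <- if (nrow(e)) m$ambiguous[k] else logical(0)
      e
    }))
    if (is.null(ev) || !nrow(ev)) return(NULL)  # no label evidence
    ev
  })
  names(tmpl) <- ukey
  nrows <- vapply(tmpl, function(x) if (is.null(x)) 0L else nrow(x),
                  integer(1))
  reps <- nrows[key]
  oi <- rep(seq_len(nrow(obs)), reps)
  if (!length(oi)) return(empty)
  flat <- do.call(rbind, tmpl[nrows > 0L])
  # row indices into `flat` for each observation, in key order
  offsets <- c(0L, cumsum(nrows[nrows > 0L]))
  names(offsets) <- c(names(nrows)[nrows > 0L], "")
  ti <- unlist(lapply(seq_len(nrow(obs))[reps > 0L], function(i) {
    o <- offsets[key[i]]
    seq.int(o + 1L, o + reps[i])
  }), use.names = FALSE)
  res <- flat[ti, , drop = FALSE]
  res$sample_id <- obs$sample_id[oi]
  res$condition_id <- obs$condition_id[oi]
  res$labelled <- obs$labelled[oi]
  res$peptide <- obs$peptide[oi]
  res$score <- obs$score[oi]
  rownames(res) <- NULL
  res[, names(empty)]
}
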