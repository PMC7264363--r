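# Proteome container and FASTA / topology I/O.
#
# A proteome is a plain data.frame with one row per protein:
#   accession  character, unique
#   sequence   uppercase amino-acid string (20 canonical letters)
#   topology   per-residue label string over {I, M, O, U}, same length as the
#              sequence ("U" = unknown/no data), or NA when never attached
# Coordinates are 1-based inclusive throughout (UniProt convention).

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct and validate a proteome table
#'
#' @param accession Character vector of unique identifiers.
#' @param sequence Character vector of amino-acid sequences (uppercased).
#' @param topology Optional character vector of per-residue topology strings
#'   over the alphabet I/M/O/U, each the same length as its sequence.
#' @return A `data.frame` of class `proteome`.
#' @export
proteome <- function(accession, sequence, topology = NA_character_) {
  accession <- as.character(accession)
  sequence <- toupper(as.character(sequence))
  if (length(topology) == 1L && length(accession) != 1L) {
    topology <- rep(topology, length(accession))
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for record(s): ",
         paste(accession[!nzchar(sequence)], collapse = ", "))
  }
  dup <- unique(accession[duplicated(accession)])
  if (length(dup)) {
    stop("duplicate accession(s): ", paste(dup, collapse = ", "))
  }
  bad <- grepl(paste0("[^", paste(.AA20, collapse = ""), "]"), sequence)
  if (any(bad)) {
    stop("non-canonical amino-acid letters in: ",
         paste(accession[bad], collapse = ", "))
  }
  df <- data.frame(accession = accession, sequence = sequence,
                   topology = topology, stringsAsFactors = FALSE)
  validate_topology(df)
  class(df) <- c("proteome", "data.frame")
  df
}

validate_topology <- function(df) {
  has <- !is.na(df$topology)
  if (any(has)) {
    if (any(grepl("[^IMOU]", df$topology[has]))) {
      stop("topology strings must use only I, M, O, U")
    }
    mism <- has & nchar(df$topology) != nchar(df$sequence)
    if (any(mism)) {
      stop("topology length differs from sequence length for: ",
           paste(df$accession[mism], collapse = ", "))
    }
  }
  invisible(df)
}

#' Read a proteome from FASTA
#'
#' Wraps [Biostrings::readAAStringSet()]; sequences are uppercased, record
#' order is preserved, and duplicate accessions or empty sequences raise an
#' error naming the offending record. The accession is the first whitespace-
#' delimited token of the header.
#'
#' @param path FASTA file (wrapped or unwrapped). An empty file yields an
#'   empty proteome.
#' @return A `proteome` data.frame (topology all `NA`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    return(proteome(character(0), character(0)))
  }
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("FASTA parse error in '", path,
                                          "': ", conditionMessage(e)))
  acc <- vapply(strsplit(names(aa), "[ \t]"), `[`, "", 1L)
  if (any(!nzchar(acc))) stop("FASTA record with empty header in ", path)
  proteome(acc, as.character(aa))
}

#' Write a proteome to FASTA
#'
#' @param prot A `proteome` data.frame.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(prot, path, width = 60L) {
  aa <- Biostrings::AAStringSet(prot$sequence)
  names(aa) <- prot$accession
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Attach per-residue topology annotations
#'
#' Reads a two-column TSV (`accession<TAB>topology-string`) in the spirit of
#' TOPDB/CCTOP per-residue annotations and attaches each string to the matching
#' protein. Proteins without a row get an all-`U` (unknown) topology; rows whose
#' accession is absent from the proteome are reported via a warning.
#'
#' @param path Topology TSV (no header).
#' @param prot A `proteome` data.frame.
#' @return The proteome with its `topology` column filled.
#' @export
read_topology <- function(path, prot) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character",
                           col.names = c("accession", "topology"))
  unmatched <- setdiff(tab$accession, prot$accession)
  if (length(unmatched)) {
    warning("topology rows for accessions absent from the proteome: ",
            paste(unmatched, collapse = ", "))
  }
  idx <- match(prot$accession, tab$accession)
  topo <- tab$topology[idx]
  topo[is.na(topo)] <- strrep("U", nchar(prot$sequence[is.na(topo)]))
  prot$topology <- topo
  validate_topology(prot)
  prot
}

#' Write topology annotations to TSV
#'
#' @param prot A `proteome` with topology attached.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(prot, path) {
  stopifnot(all(!is.na(prot$topology)))
  utils::write.table(prot[, c("accession", "topology")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Transmembrane proteins of a proteome
#'
#' A protein counts as transmembrane when its topology contains at least one
#' membrane (`M`) residue.
#'
#' @param prot A `proteome` with topology attached.
#' @return Logical vector along the proteome rows.
#' @export
is_tmp <- function(prot) {
  !is.na(prot$topology) & grepl("M", prot$topology, fixed = TRUE)
}
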