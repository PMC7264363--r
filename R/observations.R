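# Peptide observation tables: one row per modified-peptide identification in
# the style of a search-engine export.
#
# Columns:
#   sample_id  character run/sample identifier
#   enzyme     pre-digestion enzyme series: "trypsin", "chymotrypsin" or "none"
#   duration   opaque digestion-time label ("NPT", "NPC", "15min", ...); never
#              interpreted arithmetically
#   labelled   logical; FALSE marks control unlabelled preparations
#   peptide    amino-acid sequence
#   mods       semicolon-separated "pos:delta" pairs; pos is 1-based within the
#              peptide, 0 denotes the peptide N-terminal amine
#   score      search-engine confidence (LogProb-like)
# A derived column condition_id = "<enzyme>.<duration>" identifies a condition
# (enzyme series x treatment time).

.OBS_COLS <- c("sample_id", "enzyme", "duration", "labelled", "peptide",
               "mods", "score")

#' Assemble a peptide observation table
#'
#' @param sample_id,enzyme,duration,labelled,peptide,mods,score Column vectors,
#'   recycled to a common length (see the package overview for semantics).
#' @return A data.frame with a derived `condition_id` column.
#' @export
observation_table <- function(sample_id, enzyme, duration, labelled,
                              peptide, mods, score) {
  df <- data.frame(sample_id = as.character(sample_id),
                   enzyme = as.character(enzyme),
                   duration = as.character(duration),
                   labelled = as.logical(labelled),
                   peptide = toupper(as.character(peptide)),
                   mods = as.character(mods),
                   score = as.numeric(score),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$peptide))) stop("empty peptide sequence in observations")
  df$mods[is.na(df$mods)] <- ""
  ms <- strsplit(df$mods, "[;:]")
  plen <- nchar(df$peptide)
  bad <- !vapply(seq_len(nrow(df)), function(i) {
    v <- ms[[i]]
    if (!length(v) || identical(v, "")) return(TRUE)
    p <- suppressWarnings(as.integer(v[seq(1L, length(v), 2L)]))
    !anyNA(p) && all(p >= 0L & p <= plen[i])
  }, logical(1))
  if (any(bad)) {
    stop("modification position outside [0, peptide length] in row(s): ",
         paste(which(bad), collapse = ", "))
  }
  df$condition_id <- condition_id(df$enzyme, df$duration)
  df
}

condition_id <- function(enzyme, duration) paste(enzyme, duration, sep = ".")

#' Parse a modification string
#'
#' @param mods A single `"pos:delta;pos:delta"` string (may be empty).
#' @return A data.frame with integer `pos` and numeric `delta`.
#' @export
parse_mods <- function(mods) {
  if (is.na(mods) || !nzchar(mods)) {
    return(data.frame(pos = integer(0), delta = numeric(0)))
  }
  parts <- strsplit(mods, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed mods string: '", mods, "'")
  data.frame(pos = as.integer(vapply(kv, `[`, "", 1L)),
             delta = as.numeric(vapply(kv, `[`, "", 2L)))
}

format_mods <- function(pos, delta) {
  if (!length(pos)) return("")
  paste(sprintf("%d:%.4f", pos, delta), collapse = ";")
}

# vectorized: one "pos:delta" token per element
format_mods_each <- function(pos, delta) sprintf("%d:%.4f", pos, delta)

#' Read a peptide observation table
#'
#' Accepts comma- or tab-separated files with the header columns `sample_id`,
#' `enzyme`, `duration`, `labelled`, `peptide`, `mods`, `score`.
#'
#' @param path CSV/TSV file.
#' @return An observation data.frame (see [observation_table()]).
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           colClasses = "character")
  missing <- setdiff(.OBS_COLS, names(raw))
  if (length(missing)) {
    stop("peptide table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  raw$mods[is.na(raw$mods)] <- ""
  observation_table(raw$sample_id, raw$enzyme, raw$duration,
                    toupper(raw$labelled) %in% c("TRUE", "T", "1", "YES"),
                    raw$peptide, raw$mods, raw$score)
}

#' Write a peptide observation table
#'
#' @param obs An observation data.frame.
#' @param path Output path; `.csv` extension writes comma-separated, anything
#'   else tab-separated.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(obs, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(obs[, .OBS_COLS], path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
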