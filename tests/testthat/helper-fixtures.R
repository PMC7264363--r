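# Shared fixtures, built in code.

# tiny deterministic proteome used across mapping / site-calling tests
tiny_proteome <- function() {
  proteome(
    accession = c("P1", "P2"),
    sequence = c("MAKPEPTIDEKR", "MCCCCPEPTIDES"),
    topology = c("OOOOOOOOOOMI", "OOOOOOOOOMMII")
  )
}

# build an observation table with sensible defaults in one call
obs_rows <- function(peptide, mods = "", score = 5,
                     enzyme = "trypsin", duration = "15min",
                     labelled = TRUE, sample_id = "s1", n = 1L) {
  observation_table(
    sample_id = rep(sample_id, length.out = max(n, length(peptide))),
    enzyme = enzyme, duration = duration, labelled = labelled,
    peptide = rep(peptide, length.out = max(n, length(peptide))),
    mods = rep(mods, length.out = max(n, length(peptide))),
    score = rep(score, length.out = max(n, length(peptide))))
}

cam_mass <- function() label_mods()$delta_mass[2]
thio_mass <- function() label_mods()$delta_mass[1]

# moderate simulated experiment shared across test files (cached per run)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_experiment(sim_params(n_proteins = 40), seed = 101)
    }
    cache
  }
})

# random protein sequence with all 20 letters available
random_seq <- function(n, letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# independent brute-force digestion oracle: scan every residue, apply the
# cleavage rule literally, and cut the sequence
oracle_digest <- function(seq, cleave_after, block_p = TRUE,
                          blocked = integer(0)) {
  aa <- strsplit(seq, "")[[1]]
  cuts <- integer(0)
  for (p in seq_along(aa)) {
    if (p == length(aa)) next
    if (!(aa[p] %in% cleave_after)) next
    if (p %in% blocked) next
    if (block_p && aa[p + 1] == "P") next
    cuts <- c(cuts, p)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, length(aa))
  substring(seq, starts, ends)
}
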