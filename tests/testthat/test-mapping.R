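test_that("exact peptide location finds coordinates and ambiguity", {
  prot <- tiny_proteome()
  m <- locate_peptide("PEPTIDEK", prot)
  expect_identical(nrow(m), 1L)
  expect_identical(m$accession, "P1")
  expect_identical(c(m$start, m$end), c(4L, 11L))
  expect_false(m$ambiguous)
  expect_identical(nrow(suppressWarnings(locate_peptide("WWWWW", prot))), 0L)
  # present in both proteins -> every match flagged ambiguous
  amb <- locate_peptides("PEPTIDE", prot)
  expect_identical(nrow(amb), 2L)
  expect_true(all(amb$ambiguous))
})

test_that("location agrees with a naive all-offset scan on random proteomes", {
  withr::with_seed(23, {
    prot <- proteome(sprintf("R%02d", 1:6),
                     replicate(6, random_seq(sample(50:150, 1))))
    big <- prot$sequence
    for (i in 1:300) {
      src <- sample(6, 1)
      len <- sample(5:12, 1)
      start <- sample(nchar(big[src]) - len, 1)
      pep <- substr(big[src], start, start + len - 1)
      got <- locate_peptides(pep, prot)
      # oracle: test every offset of every protein
      want <- do.call(rbind, lapply(seq_len(6), function(k) {
        hits <- which(vapply(seq_len(nchar(big[k]) - len + 1), function(o) {
          substr(big[k], o, o + len - 1) == pep
        }, logical(1)))
        if (length(hits)) data.frame(accession = prot$accession[k],
                                     start = hits) else NULL
      }))
      expect_identical(got[, c("accession", "start")],
                       want[order(want$accession, want$start), ])
    }
  })
})

test_that("modification localization follows the context rules", {
  prot <- tiny_proteome()
  cfg <- pipeline_config()
  m <- locate_peptide("PEPTIDEK", prot)  # P1, 4..11
  # internal label on the terminal K: protein coordinate 4 + 8 - 1 = 11
  ev <- localize_modifications(m, data.frame(pos = 8L, delta = 145.020), prot, cfg)
  expect_identical(ev$position, 11L)
  expect_identical(ev$context, "lysine_sidechain")
  expect_true(ev$valid)
  # N-terminal label on an internal match: a pre-digestion-created N-terminus
  ev <- localize_modifications(m, data.frame(pos = 0L, delta = 87.998), prot, cfg)
  expect_identical(ev$position, 4L)
  expect_identical(ev$context, "peptide_nterm")
  # N-terminal label at residue 1: the protein's own N-terminus
  m1 <- locate_peptide("MAKPEPTI", prot)
  ev <- localize_modifications(m1, data.frame(pos = 0L, delta = 145.020), prot, cfg)
  expect_identical(ev$context, "protein_nterm")
  expect_identical(ev$position, 1L)
  # label mass on an internal non-lysine: invalid evidence, kept with reason
  ev <- localize_modifications(m, data.frame(pos = 3L, delta = 145.020), prot, cfg)
  expect_false(ev$valid)
  expect_match(ev$reason, "non-K")
  # non-label masses (deamidation) are not evidence at all
  ev <- localize_modifications(m, data.frame(pos = 5L, delta = 0.984), prot, cfg)
  expect_identical(nrow(ev), 0L)
})

test_that("initiator-methionine removal is honoured when configured", {
  prot <- tiny_proteome()
  m2 <- locate_peptide("AKPEPTID", prot)  # starts at residue 2 after Met
  ev <- localize_modifications(m2, data.frame(pos = 0L, delta = 145.02), prot,
                               pipeline_config(mature_nterm = TRUE))
  expect_identical(ev$context, "protein_nterm")
  ev <- localize_modifications(m2, data.frame(pos = 0L, delta = 145.02), prot,
                               pipeline_config(mature_nterm = FALSE))
  expect_identical(ev$context, "peptide_nterm")
})

test_that("piggyback peptides are cysteine-containing and label-free", {
  expect_true(flag_piggyback("ACDK", ""))
  expect_false(flag_piggyback("ACDK", "4:145.0198"))
  expect_false(flag_piggyback("ADGK", ""))
  # deamidation alone does not stop a peptide from being piggyback
  expect_true(flag_piggyback("ACDNK", "4:0.9840"))
})

test_that("mapping recovers simulated ground truth at the evidence level", {
  sim <- simulate_experiment(
    sim_params(n_proteins = 15, contamination_rate = 0, label_efficiency = 1,
               support_mean = 5), seed = 31)
  prot <- sim$proteome$proteome
  obs <- sim$observations[sim$observations$labelled, ]
  ev <- map_observations(filter_observations(obs), prot)
  ev <- ev[ev$valid, ]
  got <- unique(paste0(ev$condition_id, "|", ev$accession, ":", ev$position))
  t <- sim$truth[sim$truth$support_conf >= 1, ]
  want <- unique(paste0(t$condition_id, "|", t$accession, ":", t$position))
  expect_setequal(got, want)
  # every evidence row's residue is consistent with its claimed context
  k_ev <- ev[ev$context == "lysine_sidechain", ]
  expect_true(all(k_ev$residue == "K"))
})
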