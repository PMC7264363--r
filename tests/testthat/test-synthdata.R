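test_that("proteome generation is deterministic and structurally valid", {
  p1 <- generate_proteome(sim_params(n_proteins = 12), seed = 3)
  p2 <- generate_proteome(sim_params(n_proteins = 12), seed = 3)
  expect_identical(p1, p2)
  prot <- p1$proteome
  expect_true(all(nchar(prot$topology) == nchar(prot$sequence)))
  expect_true(all(substr(prot$sequence, 1, 1) == "M"))
  # identifiable peptides map uniquely: all 7-mers are proteome-unique
  kmers <- unlist(lapply(prot$sequence, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - 6), 7:n)
  }))
  expect_false(any(duplicated(kmers)))
})

test_that("single-pass proteins have one membrane block, multi-pass several", {
  one <- generate_proteome(sim_params(n_proteins = 10,
                                      single_pass_fraction = 1), seed = 5)
  blocks <- function(t) lengths(regmatches(t, gregexpr("M+", t)))
  expect_true(all(blocks(one$proteome$topology) == 1L))
  multi <- generate_proteome(sim_params(n_proteins = 10,
                                        single_pass_fraction = 0), seed = 5)
  expect_true(all(blocks(multi$proteome$topology) >= 2L))
})

test_that("ground-truth sites respect membrane protection", {
  sim <- shared_sim()
  prot <- sim$proteome$proteome
  t <- sim$truth[sim$truth$cause != "contaminant", ]
  topo_at <- substr(prot$topology[match(t$accession, prot$accession)],
                    t$position, t$position)
  expect_true(all(topo_at == "O"))
})

test_that("non-pre-digested conditions create no digestion-dependent sites", {
  sim <- shared_sim()
  npt <- sim$truth[sim$truth$condition_id %in%
                     c("trypsin.NPT", "chymotrypsin.NPC"), ]
  expect_false(any(npt$cause %in% c("new_peptide_nterm", "uncovered_lysine")))
  dig <- sim$truth[sim$truth$condition_id == "trypsin.15min", ]
  expect_true(any(dig$cause == "new_peptide_nterm"))
})

test_that("alkylated fraction of emitted labels converges to the rate", {
  sim <- shared_sim()
  lab <- sim$truth[sim$truth$cause != "contaminant", ]
  n_lab <- sum(lab$support)
  expect_gt(n_lab, 5000)
  cam_obs <- sum(lab$support[lab$mod == "CAMthiopropanoyl"])
  expect_lt(abs(cam_obs / n_lab - sim$params$alkylation_rate), 0.02)
})

test_that("nearly all observations are labelled or cysteine-containing", {
  sim <- shared_sim()
  obs <- sim$observations[sim$observations$labelled, ]
  s <- dataset_summary(obs)
  expect_gt(s$labelled_or_cys_fraction, 0.95)
})

test_that("zero label efficiency leaves only unlabelled confounders", {
  sim <- simulate_experiment(
    sim_params(n_proteins = 6, label_efficiency = 0, contamination_rate = 0),
    seed = 2)
  expect_false(any(has_label <- vapply(sim$observations$mods, function(m) {
    any(abs(parse_mods(m)$delta - 145.0198) < 0.01 |
          abs(parse_mods(m)$delta - 87.9983) < 0.01)
  }, logical(1))))
})

test_that("datasets emit and read back losslessly and reproducibly", {
  sim <- simulate_experiment(sim_params(n_proteins = 8), seed = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_dataset(sim, d1)
  emit_dataset(sim, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  back <- read_dataset(d1)
  expect_identical(nrow(back$observations), nrow(sim$observations))
  expect_identical(nrow(back$truth), nrow(sim$truth))
  expect_identical(back$proteome$sequence, sim$proteome$proteome$sequence)
  # reference topology (possibly masked) is what lands in the TSV
  expect_identical(back$proteome$topology, sim$proteome$proteome$ref_topology)
})

test_that("invalid simulation probabilities are rejected by name", {
  expect_error(sim_params(label_efficiency = 1.5), "label_efficiency")
  expect_error(sim_params(n_proteins = 0), "n_proteins")
})
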