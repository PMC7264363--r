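test_that("site classification maps topology labels to evidence classes", {
  prot <- proteome("P1", "MAKRG", "OOMMI")
  expect_identical(classify_site(rep("P1", 4), c(1L, 2L, 3L, 5L), prot),
                   c("Extracellular", "Extracellular", "Intracellular",
                     "Intracellular"))
  noto <- proteome("P2", "MAKRG")  # never annotated
  noto$topology <- NA_character_
  expect_identical(classify_site("P2", 2L, noto), "Unknown")
  expect_error(classify_site("P1", 9L, prot), "out of.*range")
  expect_error(classify_site("NOPE", 1L, prot), "unknown accession")
})

test_that("accuracy is extracellular over known-class sites, to one decimal", {
  # 164 known-class sites, 161 extracellular: accuracy rounds to 98.2%
  withr::with_seed(8, {
    topo <- paste(c("O", sample(c(rep("O", 160), rep("I", 3), rep("U", 59)))),
                  collapse = "")
    prot <- proteome("BIG", strrep("A", 223), topo)
  })
  sites <- data.frame(accession = "BIG", position = 1:223,
                      residue = "A", contexts = "lysine_sidechain",
                      ambiguous_only = FALSE, support.x = 3L,
                      stringsAsFactors = FALSE)
  v <- summarize_validation(sites, list(x = paste0("BIG:", 1:223)), prot)
  expect_identical(unname(v$merged_counts["Extracellular"]), 161L)
  expect_identical(unname(v$merged_counts["Intracellular"]), 3L)
  expect_identical(round(v$accuracy_pct, 1), 98.2)
  expect_identical(v$n_merged, 223L)
  expect_identical(sum(v$by_condition[, c("Extracellular", "Unknown",
                                          "Intracellular")]),
                   v$by_condition$n_called)
})

test_that("degenerate accuracy cases: all unknown is N/A, one of one is 100%", {
  prot <- proteome("U1", "KKKKK", "UUUUU")
  sites <- data.frame(accession = "U1", position = 1:2, residue = "K",
                      contexts = "lysine_sidechain", ambiguous_only = FALSE,
                      support.x = 3L, stringsAsFactors = FALSE)
  v <- summarize_validation(sites, list(x = c("U1:1", "U1:2")), prot)
  expect_true(is.na(v$accuracy))
  expect_output(print(v), "N/A")
  prot2 <- proteome("O1", "KKKKK", "OOOOO")
  sites2 <- data.frame(accession = "O1", position = 1L, residue = "K",
                       contexts = "lysine_sidechain", ambiguous_only = FALSE,
                       support.x = 3L, stringsAsFactors = FALSE)
  v2 <- summarize_validation(sites2, list(x = "O1:1"), prot2)
  expect_identical(v2$accuracy_pct, 100)
})

test_that("clean simulations validate fully extracellular; contamination shows up", {
  sim <- simulate_experiment(
    sim_params(n_proteins = 15, contamination_rate = 0, label_efficiency = 1,
               support_mean = 5), seed = 77)
  run <- run_pipeline(sim$proteome$proteome, sim$observations)
  expect_identical(sum(run$validation$by_condition$Intracellular), 0L)
  # heavy contamination with passable scores must surface intracellular calls
  dirty <- simulate_experiment(
    sim_params(n_proteins = 60, contamination_rate = 0.5,
               score_mu_false = 3, support_mean = 5), seed = 78)
  drun <- run_pipeline(dirty$proteome$proteome, dirty$observations)
  expect_gt(sum(drun$validation$by_condition$Intracellular), 0L)
})

test_that("mechanism fractions behave at their limit cases", {
  sim <- shared_sim()
  run <- run_pipeline(sim$proteome$proteome, sim$observations,
                      truth = sim$truth)
  m <- run$mechanism
  expect_true(m$nterm_digest_only_fraction > 0 &&
                m$nterm_digest_only_fraction <= 1)
  expect_true(m$site_digest_only_fraction > 0 &&
                m$site_digest_only_fraction < 1)
  # without pre-digestion there is nothing digestion-specific to find
  expect_warning(m0 <- mechanism_stats(run$evidence, run$called, character(0)),
                 "no pre-digested")
  expect_identical(m0$site_digest_only_fraction, 0)
  # no surface cutting -> no digest-only sites
  flat <- simulate_experiment(
    sim_params(n_proteins = 12, contamination_rate = 0, label_efficiency = 1,
               support_mean = 5),
    conditions = default_conditions(p_cleave = c(0, 0)), seed = 9)
  frun <- run_pipeline(flat$proteome$proteome, flat$observations)
  expect_identical(frun$mechanism$site_digest_only_fraction, 0)
})

test_that("constraint files round-trip the called extracellular set", {
  sim <- simulate_experiment(sim_params(n_proteins = 10), seed = 12)
  run <- run_pipeline(sim$proteome$proteome, sim$observations)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_constraints(run$sites, run$called, f)
  back <- read_constraints(f)
  expect_true(all(back$label == "O"))
  expect_setequal(paste0(back$accession, ":", back$position),
                  unique(unlist(run$called)))
  # positions sorted within accession
  expect_false(is.unsorted(order(back$accession, back$position)))
})
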