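test_that("score and label-mass filtering follows the stated semantics", {
  cam <- sprintf("4:%0.4f", cam_mass())
  obs <- obs_rows(
    peptide = rep("PEPKAR", 4),
    mods = c(cam, cam, "2:0.9840", cam),
    score = c(2.0, 1.9, 3.0, 5.0))
  kept <- filter_observations(obs)
  # boundary score 2.0 is retained (inclusive threshold)
  expect_identical(nrow(kept), 2L)
  expect_true(all(kept$score >= 2))
  rm <- attr(kept, "removed")
  expect_identical(unname(rm["score_below"]), 1L)
  expect_identical(unname(rm["no_label_mod"]), 1L)  # deamidation-only row
})

test_that("support aggregation calls sites at the minimum-support rule", {
  prot <- tiny_proteome()
  cam <- sprintf("8:%0.4f", cam_mass())
  obs <- rbind(
    obs_rows("PEPTIDEK", cam, score = 5, n = 3),               # K11, 3x
    obs_rows("MAKPEPTI", sprintf("0:%0.4f", thio_mass()),
             score = 5, n = 2))                                # Nterm, 2x
  ev <- map_observations(obs, prot)
  sites <- aggregate_sites(ev)
  expect_identical(nrow(sites), 2L)
  called3 <- called_sets(sites, 3L)[["trypsin.15min"]]
  expect_identical(called3, "P1:11")
  called1 <- called_sets(sites, 1L)[["trypsin.15min"]]
  expect_setequal(called1, c("P1:11", "P1:1"))
})

test_that("support can be counted as distinct peptide sequences", {
  prot <- tiny_proteome()
  cam <- sprintf("8:%0.4f", cam_mass())
  obs <- obs_rows("PEPTIDEK", cam, score = 5, n = 3)
  ev <- map_observations(obs, prot)
  s_psm <- aggregate_sites(ev, pipeline_config(support_unit = "observations"))
  s_pep <- aggregate_sites(ev, pipeline_config(support_unit = "distinct_peptides"))
  expect_identical(s_psm[["support.trypsin.15min"]], 3L)
  expect_identical(s_pep[["support.trypsin.15min"]], 1L)
})

test_that("a site keeps every context observed across its evidence", {
  prot <- tiny_proteome()
  obs <- rbind(
    obs_rows("KPEPTIDEK", sprintf("1:%0.4f", cam_mass()), score = 5),
    obs_rows("KPEPTIDEK", sprintf("0:%0.4f", cam_mass()), score = 5))
  ev <- map_observations(obs, prot)
  sites <- aggregate_sites(ev)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$contexts, "lysine_sidechain,peptide_nterm")
})

test_that("control subtraction removes only well-supported control sites", {
  prot <- tiny_proteome()
  cam <- sprintf("8:%0.4f", cam_mass())
  obs <- obs_rows("PEPTIDEK", cam, score = 5, n = 3)
  sites <- aggregate_sites(map_observations(obs, prot))
  ctrl3 <- map_observations(
    obs_rows("PEPTIDEK", cam, score = 5, n = 3, labelled = FALSE,
             enzyme = "none", duration = "unlabelled"), prot)
  ctrl1 <- ctrl3[1, , drop = FALSE]
  expect_identical(nrow(subtract_control(sites, ctrl3)), 0L)
  expect_identical(nrow(subtract_control(sites, ctrl1)), 1L)
  expect_identical(subtract_control(sites, NULL), sites,
                   ignore_attr = TRUE)
})

test_that("condition comparison partitions exactly like set algebra", {
  called <- list(a.NPT = c("s1", "s2"), a.15 = c("s2", "s3"))
  cmp <- compare_conditions(called,
                            list(a = list(control = "a.NPT", digest = "a.15")))
  cc <- cmp$a$counts
  expect_identical(unname(cc[c("control_only", "shared", "digest_only")]),
                   c(1L, 1L, 1L))
  expect_identical(unname(cc["union"]),
                   unname(cc["control_only"] + cc["shared"] + cc["digest_only"]))
  # identical and disjoint limits
  same <- compare_conditions(list(x = c("a", "b"), y = c("a", "b")),
                             list(s = list(control = "x", digest = "y")))
  expect_identical(unname(same$s$counts["shared"]), 2L)
  disj <- compare_conditions(list(x = "a", y = "b"),
                             list(s = list(control = "x", digest = "y")))
  expect_identical(unname(disj$s$counts["shared"]), 0L)
})

test_that("protein/position counts separate TM from non-TM proteins", {
  prot <- proteome(c("T1", "N1"), c("MAKPEPTIDEKR", "MAKPEPTLDEKR"),
                   c("OOOOOOOOOOMI", "OOOOOOOOOOOO"))
  cam <- sprintf("8:%0.4f", cam_mass())
  obs <- rbind(obs_rows("PEPTIDEK", cam, score = 5, n = 3),
               obs_rows("KPEPTIDE", sprintf("1:%0.4f", cam_mass()),
                        score = 5, n = 3),
               obs_rows("PEPTLDEK", cam, score = 5, n = 3))
  sites <- aggregate_sites(map_observations(obs, prot))
  called <- called_sets(sites, 3L)
  counts <- summarize_counts(sites, called, prot)
  expect_identical(counts$tmp_proteins, 1L)
  expect_identical(counts$tmp_positions, 2L)  # two positions on T1
  expect_identical(counts$nontmp_proteins, 1L)
  expect_identical(counts$nontmp_positions, 1L)
})

test_that("raising the support threshold never grows a called set", {
  sim <- shared_sim()
  run_obs <- sim$observations[sim$observations$labelled, ]
  ev <- map_observations(filter_observations(run_obs),
                         sim$proteome$proteome)
  sites <- aggregate_sites(ev)
  prev <- NULL
  for (ms in 1:5) {
    cur <- called_sets(sites, ms)
    if (!is.null(prev)) {
      for (cid in names(cur)) {
        expect_true(all(cur[[cid]] %in% prev[[cid]]))
      }
    }
    prev <- cur
  }
})
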