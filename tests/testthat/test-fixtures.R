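# Packaged fixtures: the lead, the toy receptor, mock reports and the
# smoke configuration.

test_that("the lead structure has the constitution of the named ligand", {
  lead <- lead_structure()
  expect_equal(length(lead$elem), 24L)
  expect_equal(sum(lead$elem == "N"), 6L)
  expect_equal(sum(lead$elem == "C"), 18L)
  # three linked/fused aromatic ring systems, five rings in total
  expect_equal(leadopt:::n_aromatic_rings(lead), 5L)
  arom_sub <- sum(lead$arom_atom)
  expect_equal(arom_sub, 24L)      # every atom aromatic
  expect_identical(to_canonical_smiles(lead_structure()),
                   to_canonical_smiles(lead_structure()))
})

test_that("the toy receptor parses cleanly with the advertised residues", {
  f <- toy_receptor()
  expect_silent(pdb <- bio3d::read.pdb(f, verbose = FALSE))
  at <- pdb$atom
  expect_setequal(paste0(at$resid, "-", at$resno),
                  c(rep("ARG-515", 11), rep("ASN-519", 8),
                    rep("LYS-520", 9)))
  # side chains carry the contact atoms of interest
  expect_true(any(at$resno == 519 & trimws(at$elety) == "OD1"))
  expect_true(any(at$resno == 520 & trimws(at$elety) == "NZ"))
  expect_true(any(at$resno == 515 & trimws(at$elety) == "NH1"))
})

test_that("mock engine reports embed the given energies in both dialects", {
  rep <- mock_engine_report(1L, -6.55)
  expect_equal(min(parse_vina_report(rep$vina)$energy), -6.55)
  expect_equal(parse_dlg_report(rep$dlg)$energy, -6.55)

  set.seed(12)
  e20 <- round(runif(20, -12, -4), 2)
  r20 <- mock_engine_report(20L, e20)
  v <- parse_vina_report(r20$vina)
  expect_equal(v$energy, e20)               # parser keeps report order
  expect_equal(sort(v$energy), sort(e20))
  expect_error(mock_engine_report(0L, numeric(0)), ">= 1")
  expect_error(mock_engine_report(3L, c(-1, -2)), "length")
})

test_that("the smoke configuration matches its documented conditions", {
  cfg <- seeded_smoke_config()
  expect_equal(cfg$agent$episodes, 200L)
  expect_equal(cfg$mdp$step_limit, 8L)
  expect_identical(cfg$reward$affinity, "surrogate")
  expect_identical(epsilon_at(0, cfg$agent), 1.0)
  expect_identical(epsilon_at(200, cfg$agent), 0.0)
  expect_identical(epsilon_at(100, cfg$agent), 0.5)
  # the study-scale defaults remain on the plain constructor
  d <- agent_config()
  expect_equal(d$episodes, 6000L)
  expect_equal(d$epsilon_den, 6000)
  expect_equal(d$fp_width, 2048L)
  expect_equal(d$hidden, c(1024L, 512L))
})

test_that("surrogate parameters are shaped as documented", {
  p <- surrogate_params()
  expect_lt(p$donor_bonus_kcal, 0)
  expect_gte(p$size_penalty_kcal, 0)
  expect_true(all(c("C", "N", "O") %in% names(p$element_kcal)))
  # the lead lands near the modal affinity of the optimized episodes
  expect_equal(surrogate_affinity(lead_structure(), p), -8.1,
               tolerance = 0.5)
})
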