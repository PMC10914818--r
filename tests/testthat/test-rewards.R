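# Reward evaluators: QED, normalized synthetic accessibility, the
# deterministic surrogate affinity, and the docking-report parsers.
#
# Reference values marked "independent reference" were computed with the
# standard rdkit implementations of QED and the fragment-contribution SA
# score on the same SMILES.

test_that("QED of the lead matches its reported value", {
  q <- qed_score(lead_structure())
  expect_gt(q, 0.45); expect_lt(q, 0.55)        # reported 0.5
  expect_equal(q, 0.5022, tolerance = 1e-3)     # independent reference
})

test_that("QED descriptors and score match an independent reference for benzene", {
  p <- qed_properties(parse_smiles("c1ccccc1"))
  expect_equal(unname(p["HBA"]), 0)
  expect_equal(unname(p["HBD"]), 0)
  expect_equal(unname(p["ROTB"]), 0)
  expect_equal(unname(p["AROM"]), 1)
  expect_equal(unname(p["ALERTS"]), 0)
  expect_equal(unname(p["PSA"]), 0)
  expect_equal(qed_score(parse_smiles("c1ccccc1")), 0.44263,
               tolerance = 1e-3)                # independent reference
})

test_that("QED lies strictly inside (0,1) and is a pure function", {
  set.seed(2)
  smis <- replicate(6, random_valid_smiles())
  for (s in smis) {
    m <- parse_smiles(s)
    q1 <- qed_score(m)
    expect_gt(q1, 0); expect_lt(q1, 1)
    expect_identical(q1, qed_score(parse_smiles(s)))
  }
})

test_that("normalized SA of the lead matches its reported value", {
  m <- lead_structure()
  raw <- sa_score_raw(m)
  expect_equal(raw, 2.3211, tolerance = 5e-3)   # independent reference
  s <- sa_score(m)
  expect_gt(s, 0.80); expect_lt(s, 0.90)        # reported 0.85
})

test_that("SA rescaling is exact at the endpoints and monotone", {
  expect_equal(sa_normalize(10), 0)
  expect_equal(sa_normalize(1), 1)
  raws <- seq(1, 10, by = 0.5)
  expect_true(all(diff(sa_normalize(raws)) < 0))
})

test_that("SA matches the independent reference on known molecules", {
  refs <- c("CC" = 2.748, "CCO" = 1.980, "c1ccccc1" = 1.000,
            "CC(=O)Oc1ccccc1C(=O)O" = 1.580,
            "Cn1cnc2c1c(=O)n(C)c(=O)n2C" = 2.298)
  for (smi in names(refs))
    expect_equal(sa_score_raw(parse_smiles(smi)), unname(refs[smi]),
                 tolerance = 5e-3, label = smi)
  expect_gt(sa_score(parse_smiles("CC")), 0.8)  # ethane is easy to make
})

test_that("repeated reward calls agree bitwise", {
  m <- parse_smiles("CC(=O)Nc1ccc(O)cc1")
  q <- replicate(20, qed_score(m))
  s <- replicate(20, sa_score(m))
  expect_length(unique(q), 1L)
  expect_length(unique(s), 1L)
})

test_that("the surrogate oracle is deterministic and additive", {
  m <- parse_smiles("C")
  p <- surrogate_params()
  expect_identical(surrogate_affinity(m, p), surrogate_affinity(m, p))
  expect_equal(surrogate_affinity(m, p), p$element_kcal[["C"]])

  # an extra H-bond donor strictly improves (lowers) the score
  plain <- parse_smiles("Cc1ccccc1")
  donor <- parse_smiles("NCc1ccccc1")
  no_donor_add <- parse_smiles("CCc1ccccc1")
  expect_lt(surrogate_affinity(donor, p), surrogate_affinity(plain, p))
  expect_lt(surrogate_affinity(donor, p),
            surrogate_affinity(no_donor_add, p))

  # lead value reproduced by an independent hand sum over its atoms
  lead <- lead_structure()
  hand <- 18 * p$element_kcal[["C"]] + 6 * p$element_kcal[["N"]]
  expect_equal(surrogate_affinity(lead, p), hand)
  expect_gt(hand, -14); expect_lt(hand, 0)
})

test_that("greedy hill-climbing improves the surrogate from the lead", {
  cfg <- mdp_config(step_limit = 8L)
  lead <- lead_structure()
  set.seed(31)
  improved <- 0L
  for (trial in 1:50) {
    s <- initial_state(lead, cfg)
    cands <- enumerate_actions(s, cfg)
    vals <- vapply(cands, surrogate_affinity, 0)
    base <- surrogate_affinity(lead)
    # greedy: the best single edit from a random subset of the actions
    sub <- sample(seq_along(cands), 20L)
    if (min(vals[sub]) < base) improved <- improved + 1L
  }
  expect_gte(improved, 45L)   # >= 90% of seeded single-step trials
})

test_that("scalarized rewards combine the three components", {
  rv <- reward_vector(lead_structure())
  expect_true(rv$qed >= 0 && rv$qed <= 1)
  expect_true(rv$sa >= 0 && rv$sa <= 1)
  expect_true(is.finite(rv$affinity))
  expect_equal(rv$scalar, -rv$affinity / 10 + rv$qed + rv$sa)
})

test_that("engine-report parsing returns the minimum as the affinity", {
  rep <- mock_engine_report(5L, c(-6.55, -6.1, -5.9, -5.0, -4.2))
  v <- parse_vina_report(rep$vina)
  expect_equal(nrow(v), 5L)
  expect_equal(min(v$energy), -6.55)
  d <- parse_dlg_report(rep$dlg)
  expect_equal(d$energy, c(-6.55, -6.1, -5.9, -5.0, -4.2))

  # cached docking affinity equals the minimum of the report energies
  box <- build_grid_box(c(20, 20, 20), 0.375, c(0, 0, 0))
  eng <- engine_config("mock", runner = function(conf, rec, box, n, e)
    mock_engine_report(3L, c(-5.5, -7.25, -6.0))$vina)
  rec <- toy_receptor()
  m <- parse_smiles("CCO")
  a1 <- docking_affinity(m, rec, box, poses = 3L, engine = eng)
  expect_equal(a1, -7.25)
  expect_identical(docking_affinity(m, rec, box, poses = 3L, engine = eng),
                   a1)
})
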