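# Molecule-modification MDP: state mechanics and the four action
# families.

cfg16 <- mdp_config(step_limit = 16L)

test_that("initial states wrap the unmodified lead with a full clock", {
  s <- initial_state(lead_structure(), cfg16)
  expect_equal(s$steps_taken, 0L)
  expect_equal(s$step_limit - s$steps_taken, 16L)
  expect_false(is_terminal(s))

  s1 <- initial_state(parse_smiles("C"), mdp_config(step_limit = 1L))
  expect_equal(s1$step_limit, 1L)
  expect_error(mdp_config(step_limit = 0L), ">= 1")
  expect_error(initial_state(structure(list(), class = "molecule"), cfg16))
})

test_that("methane expands to exactly the nine spec'd candidates", {
  s <- initial_state(parse_smiles("C"), cfg16)
  cands <- enumerate_actions(s, cfg16)
  smis <- sort(canonical_smiles(lapply(cands, function(m) {
    attr(m, "cansmi") <- NULL; m
  })))
  expect_equal(smis, sort(c("C", "CC", "C=C", "C#C", "CN", "C=N", "C#N",
                            "CO", "C=O")))
})

test_that("bond-order increments appear exactly once for ethane", {
  s <- initial_state(parse_smiles("CC"), cfg16)
  smis <- canonical_smiles(lapply(enumerate_actions(s, cfg16),
                                  function(m) { attr(m, "cansmi") <- NULL; m }))
  expect_equal(sum(smis == "C=C"), 1L)
  expect_true("CC" %in% smis)      # no-modification present
})

test_that("every candidate set contains the unmodified molecule", {
  set.seed(3)
  for (i in 1:10) {
    m <- parse_smiles(random_valid_smiles())
    s <- initial_state(m, cfg16)
    keys <- vapply(enumerate_actions(s, cfg16), leadopt:::mol_key, "")
    expect_true(leadopt:::mol_key(m) %in% keys)
  }
})

test_that("candidates are valence-valid, unique and aromatic-frozen", {
  lead <- lead_structure()
  s <- initial_state(lead, cfg16)
  cands <- enumerate_actions(s, cfg16)
  keys <- vapply(cands, leadopt:::mol_key, "")
  expect_equal(anyDuplicated(keys), 0L)
  for (m in cands) {
    expect_true(isTRUE(validate_molecule(m)))
    # aromatic bonds are frozen: they survive unless a whole fragment was
    # discarded by a disconnecting deletion
    if (length(m$elem) >= 24L) expect_equal(sum(m$arom), 26L)
    else expect_equal(sum(m$arom), 16L)   # one benzimidazole dropped
  }
  smis <- canonical_smiles(lapply(cands, function(m) {
    attr(m, "cansmi") <- NULL; m
  }))
  expect_equal(anyDuplicated(smis), 0L)
})

test_that("stepping increments the clock, terminates at the limit and rejects illegal actions", {
  cfg2 <- mdp_config(step_limit = 2L)
  s <- initial_state(parse_smiles("CC"), cfg2)
  cands <- enumerate_actions(s, cfg2)
  s2 <- mdp_step(s, cands[[2L]], cfg2)
  expect_equal(s2$steps_taken, 1L)
  expect_false(is_terminal(s2))

  # no-modification keeps the molecule but advances the clock
  nomod <- Filter(function(m)
    leadopt:::mol_key(m) == leadopt:::mol_key(s$mol), cands)[[1L]]
  s3 <- mdp_step(s, nomod, cfg2)
  expect_identical(to_canonical_smiles(s3$mol), to_canonical_smiles(s$mol))
  expect_equal(s3$steps_taken, 1L)

  cands2 <- enumerate_actions(s2, cfg2)
  s4 <- mdp_step(s2, cands2[[1L]], cfg2)
  expect_true(is_terminal(s4))
  expect_error(enumerate_actions(s4, cfg2), "terminal")
  expect_error(mdp_step(s, parse_smiles("c1ccccc1CCCC"), cfg2),
               "not a legal action")
})

test_that("bond deletion keeps the largest fragment connected", {
  # ethylbenzene: deleting the exocyclic C-C bond must keep the ring
  m <- parse_smiles("CCc1ccccc1")
  s <- initial_state(m, cfg16)
  cands <- enumerate_actions(s, cfg16)
  sizes <- vapply(cands, function(x) length(x$elem), 0L)
  expect_true(all(vapply(cands, leadopt:::is_connected, TRUE)))
  expect_true(any(sizes == 7L))    # ring + one carbon from splitting CC
  expect_true(all(sizes >= 4L))    # never the small fragment
})

test_that("enumeration matches the brute-force oracle on random molecules", {
  set.seed(19)
  for (i in 1:12) {
    smi <- random_valid_smiles(6L)
    m <- parse_smiles(smi)
    expect_identical(impl_action_smiles(m, cfg16),
                     brute_force_actions(m),
                     info = smi)
  }
})

test_that("structural-key dedup agrees with canonical-SMILES dedup", {
  cfg_can <- mdp_config(step_limit = 16L, dedup = "canonical")
  set.seed(23)
  mols <- c(list(lead_structure()),
            lapply(replicate(6, random_valid_smiles()), parse_smiles))
  for (m in mols) {
    a <- impl_action_smiles(m, cfg16)
    b <- impl_action_smiles(m, cfg_can)
    expect_identical(a, b)
  }
})

test_that("episodes stay within the edit budget", {
  cfg4 <- mdp_config(step_limit = 4L)
  set.seed(5)
  lead <- parse_smiles("CCO")
  s <- initial_state(lead, cfg4)
  edits <- 0L
  while (!is_terminal(s)) {
    cands <- enumerate_actions(s, cfg4)
    pick <- cands[[sample.int(length(cands), 1L)]]
    if (leadopt:::mol_key(pick) != leadopt:::mol_key(s$mol))
      edits <- edits + 1L
    s <- mdp_step(s, pick, cfg4, candidates = cands)
  }
  expect_lte(edits, 4L)
  expect_equal(s$steps_taken, 4L)
})
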