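# Molecular graph core: parsing, valence bookkeeping, canonical
# serialization, ring perception.

test_that("parsing recovers atom counts, hydrogens and valence", {
  m <- parse_smiles("C")
  expect_s3_class(m, "molecule")
  expect_equal(length(m$elem), 1L)
  expect_equal(m$nH, 4L)

  lead <- lead_structure()
  expect_equal(length(lead$elem), 24L)
  expect_equal(sum(lead$elem == "N"), 6L)
  expect_true(isTRUE(validate_molecule(lead)))
  expect_equal(sum(lead$arom), 26L)
})

test_that("invalid SMILES are rejected with informative errors", {
  expect_error(parse_smiles(""), "non-empty")
  expect_error(parse_smiles("C(=O)(=O)(=O)C"), "valence")
  expect_error(parse_smiles("C1CC"), "cannot parse")
  expect_error(parse_smiles("C!C"), "token")
})

test_that("canonical SMILES is idempotent and permutation-invariant", {
  lead_smi <- to_canonical_smiles(lead_structure())
  expect_identical(to_canonical_smiles(parse_smiles(lead_smi)), lead_smi)

  # atom-order permutations of benzene and of a branched molecule
  perms <- c("c1ccccc1", "C1=CC=CC=C1")
  smi <- vapply(perms, function(s) to_canonical_smiles(parse_smiles(s)), "")
  expect_length(unique(smi), 1L)

  alt <- c("CC(N)C(=O)O", "OC(=O)C(C)N", "NC(C)C(O)=O")
  smi2 <- vapply(alt, function(s) to_canonical_smiles(parse_smiles(s)), "")
  expect_length(unique(smi2), 1L)
})

test_that("free valence follows the replaceable-hydrogen convention", {
  expect_equal(free_valence(parse_smiles("C"), 1), 4L)
  e <- parse_smiles("CCO")
  expect_equal(free_valence(e, 3), 1L)   # hydroxyl oxygen
  b <- parse_smiles("c1ccccc1")
  expect_equal(free_valence(b, 1), 1L)   # aromatic CH can be substituted
  expect_error(free_valence(b, 99), "out of range")
})

test_that("free-valence bookkeeping balances against the valence table", {
  set.seed(42)
  for (i in 1:25) {
    m <- parse_smiles(random_valid_smiles())
    bs <- bf_bond_sums(unclass(m))
    perm <- c(C = 4L, N = 3L, O = 2L)[m$elem]
    expect_equal(bs + m$nH, unname(perm))
  }
})

test_that("parse-serialize-parse is stable over a random corpus", {
  set.seed(7)
  smis <- replicate(100, random_valid_smiles())
  for (s in smis) {
    m <- parse_smiles(s)
    s2 <- to_canonical_smiles(m)
    m2 <- parse_smiles(s2)
    expect_identical(to_canonical_smiles(m2), s2)
    expect_equal(length(m2$elem), length(m$elem))
    expect_equal(sort(table(m2$elem)), sort(table(m$elem)))
    expect_true(isTRUE(validate_molecule(m2)))
  }
})

test_that("ring perception identifies aromatic systems and ring features", {
  lead <- lead_structure()
  expect_equal(leadopt:::n_aromatic_rings(lead), 5L)
  rf <- leadopt:::ring_features(lead)
  expect_equal(rf$n_rings, 5L)
  expect_equal(rf$n_spiro, 0L)
  expect_equal(rf$n_bridgeheads, 0L)

  expect_equal(leadopt:::ring_features(parse_smiles("C1CCC2(CC1)CCCC2"))$n_spiro, 1L)
  expect_equal(leadopt:::ring_features(parse_smiles("C1CC2CCC1CC2"))$n_bridgeheads, 2L)
  expect_equal(leadopt:::ring_features(parse_smiles("C1CCCCCCCCC1"))$n_macrocycles, 1L)
  inring <- leadopt:::ring_membership(parse_smiles("CC1CC1"))
  expect_equal(inring, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("structural keys separate non-isomorphic molecules and unite relabelings", {
  expect_identical(leadopt:::mol_key(parse_smiles("OC(=O)C(C)N")),
                   leadopt:::mol_key(parse_smiles("NC(C)C(O)=O")))
  expect_false(identical(leadopt:::mol_key(parse_smiles("c1ccccc1")),
                         leadopt:::mol_key(parse_smiles("c1ccncc1"))))
  set.seed(11)
  smis <- unique(replicate(40, random_valid_smiles()))
  keys <- vapply(smis, function(s) leadopt:::mol_key(parse_smiles(s)), "")
  expect_equal(anyDuplicated(keys), 0L)
})
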