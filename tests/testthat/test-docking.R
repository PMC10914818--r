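# Docking validation: grid box, receptor preparation, pose handling and
# hydrogen-bond contact analysis.

test_that("the grid box derives physical extents and validates input", {
  box <- build_grid_box(c(80, 60, 60), 0.375, c(23.895, 49.094, 134.275))
  expect_equal(box$npts, c(80L, 60L, 60L))
  expect_equal(box$extent, c(30.0, 22.5, 22.5))
  expect_equal(box$center, c(23.895, 49.094, 134.275))
  expect_error(build_grid_box(c(80, 60, 60), 0, c(0, 0, 0)), "positive")
  expect_error(build_grid_box(c(80, 60), 0.375, c(0, 0, 0)), "three")

  lines <- grid_parameter_lines(box)
  expect_identical(lines, c("npts 80 60 60", "spacing 0.375",
                            "gridcenter 23.895 49.094 134.275"))
})

test_that("receptor preparation strips waters and preserves numbering", {
  rec <- toy_receptor()
  prep <- prepare_receptor(rec)
  expect_setequal(unique(prep$pdb$atom$resno), c(515L, 519L, 520L))

  # add waters and a nonstandard residue
  lines <- attr(rec, "text")
  extra <- c(
    "HETATM 9000  O   HOH A 900      40.000  40.000  40.000  1.00  0.00           O",
    "ATOM   9001  C1  LIG A 901      41.000  41.000  41.000  1.00  0.00           C")
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c(lines[-length(lines)], extra, "END"), f2)
  expect_warning(prep2 <- prepare_receptor(f2), "LIG")
  expect_false(any(prep2$pdb$atom$resid == "HOH"))
  expect_true(any(prep2$pdb$atom$resid == "LIG"))
  out <- readLines(prep2$path)
  expect_false(any(grepl("HOH", out)))

  expect_error(prepare_receptor("no/such/file.pdb"), "no such file")
})

test_that("docking returns energy-sorted poses with stable ties", {
  box <- build_grid_box(c(40, 40, 40), 0.375, c(5, 0, 10))
  rec <- toy_receptor()
  energies <- c(-5.1, -7.2, -6.3, -7.2, -4.0)   # one exact tie pair
  eng <- engine_config("mock", runner = function(conf, r, b, n, e)
    mock_engine_report(5L, energies)$vina)
  ps <- dock(parse_smiles("CCO"), rec, box, poses = 5L, engine = eng)
  expect_length(ps, 5L)
  expect_equal(vapply(ps, `[[`, 0, "energy"),
               c(-7.2, -7.2, -6.3, -5.1, -4.0))
  expect_equal(ps[[1]]$rank, 1L)

  # fewer poses than requested warns but returns what came back
  eng3 <- engine_config("mock", runner = function(conf, r, b, n, e)
    mock_engine_report(3L, c(-6, -5, -4))$dlg)
  expect_warning(ps3 <- dock(parse_smiles("CCO"), rec, box, poses = 20L,
                             engine = eng3), "3 pose")
  expect_length(ps3, 3L)
})

test_that("hydrogen bonds are detected, classed, and geometric", {
  rec <- bio3d::read.pdb(toy_receptor(), verbose = FALSE)

  # the constructed 1.9-A hydroxyl contact: exactly one, strong, at ASN-519
  pose <- toy_probe_pose(1.9)
  hb <- detect_hbonds(pose, rec)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$residue, "ASN-519")
  expect_equal(hb$class, "strong")
  expect_equal(hb$distance, 1.9, tolerance = 0.05)

  # a 3.3-A contact is "moderate"
  hb33 <- detect_hbonds(toy_probe_pose(3.3), rec)
  expect_equal(nrow(hb33), 1L)
  expect_equal(hb33$class, "moderate")
  expect_equal(hb33$distance, 3.3, tolerance = 0.05)

  # out of range at 5.0 A under the 3.5-A cutoff
  expect_equal(nrow(detect_hbonds(toy_probe_pose(5.0), rec)), 0L)
})

test_that("reported distances recompute from raw coordinates", {
  rec <- bio3d::read.pdb(toy_receptor(), verbose = FALSE)
  pose <- toy_probe_pose(2.6)
  hb <- detect_hbonds(pose, rec)
  expect_equal(hb$class, "moderate")
  od1 <- rec$atom[rec$atom$resno == 519 & trimws(rec$atom$elety) == "OD1", ]
  d <- sqrt(sum((pose$xyz[2, ] - as.numeric(od1[c("x", "y", "z")]))^2))
  expect_equal(hb$distance, d, tolerance = 1e-6)
})

test_that("contact detection is cutoff-monotone and scan-order symmetric", {
  rec <- bio3d::read.pdb(toy_receptor(), verbose = FALSE)
  pose <- toy_probe_pose(3.0)
  wide <- detect_hbonds(pose, rec, hbond_config(cutoff = 3.5))
  narrow <- detect_hbonds(pose, rec, hbond_config(cutoff = 2.0))
  expect_lte(nrow(narrow), nrow(wide))
  expect_true(all(narrow$distance <= 2.0))

  # symmetric under which structure is scanned first: a receptor-donor
  # contact (LYS NZ near a ligand acceptor) is found regardless
  nz <- leadopt:::.toy_atom_xyz(520L, "NZ")
  lig <- parse_smiles("C=O")       # acceptor-only oxygen
  pose2 <- structure(list(
    xyz = rbind(nz + c(2.4 + 1.2, 0, 0), nz + c(2.4, 0, 0)),
    elem = c("C", "O"), mol = lig), class = "docking_pose")
  hb2 <- detect_hbonds(pose2, rec)
  expect_true(any(hb2$donor_owner == "receptor" &
                  hb2$residue == "LYS-520"))
})

test_that("a frame mismatch between pose and box is flagged", {
  rec <- bio3d::read.pdb(toy_receptor(), verbose = FALSE)
  pose <- toy_probe_pose(1.9)
  far_box <- build_grid_box(c(40, 40, 40), 0.375, c(500, 500, 500))
  expect_warning(detect_hbonds(pose, rec, box = far_box), "frame")
})
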