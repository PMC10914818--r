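# Synthetic stand-ins for every external input, so the full pipeline runs
# and is tested offline: the lead structure, a toy receptor with the
# contact residues of the docking analysis (ARG-515, ASN-519, LYS-520), a
# probe ligand pose constructed at a known hydrogen-bond distance, mock
# engine reports in both supported dialects, and a seeded smoke-scale run
# configuration.

.LEAD_SMILES <- "c1ccc2c(c1)ncn2-c1ccc(nn1)-n1cnc2ccccc21"

#' The lead structure
#'
#' 3,6-bis(benzimidazol-1-yl)pyridazine: the free organic ligand of the
#' synthesized complex, used as the optimization template (24 heavy
#' atoms, 6 nitrogens, two benzimidazoles linked to a pyridazine).
#'
#' @return a validated `molecule`.
#' @export
lead_structure <- function() {
  parse_smiles(.LEAD_SMILES)
}

# Idealized side-chain templates, backbone at the origin.  Coordinates are
# synthetic (plausible bond lengths, not crystallographic).
.RESIDUE_TEMPLATES <- list(
  ARG = rbind(
    N   = c(-1.46,  0.00, 0.00),
    CA  = c( 0.00,  0.00, 0.00),
    C   = c( 0.53,  1.42, 0.00),
    O   = c( 1.73,  1.64, 0.00),
    CB  = c( 1.50, -0.50, 0.00),
    CG  = c( 2.90, -1.00, 0.20),
    CD  = c( 4.30, -0.60, 0.30),
    NE  = c( 5.60, -1.20, 0.40),
    CZ  = c( 6.90, -0.80, 0.40),
    NH1 = c( 7.20,  0.50, 0.30),
    NH2 = c( 7.90, -1.70, 0.50)),
  ASN = rbind(
    N   = c(-1.46,  0.00, 0.00),
    CA  = c( 0.00,  0.00, 0.00),
    C   = c( 0.53,  1.42, 0.00),
    O   = c( 1.73,  1.64, 0.00),
    CB  = c( 1.50, -0.50, 0.00),
    CG  = c( 2.90, -1.00, 0.10),
    OD1 = c( 3.90, -0.20, 0.10),
    ND2 = c( 3.10, -2.30, 0.20)),
  LYS = rbind(
    N   = c(-1.46,  0.00, 0.00),
    CA  = c( 0.00,  0.00, 0.00),
    C   = c( 0.53,  1.42, 0.00),
    O   = c( 1.73,  1.64, 0.00),
    CB  = c( 1.50, -0.50, 0.00),
    CG  = c( 2.90, -1.00, 0.10),
    CD  = c( 4.30, -0.60, 0.20),
    CE  = c( 5.70, -1.10, 0.30),
    NZ  = c( 7.00, -0.60, 0.40)))

.TOY_LAYOUT <- data.frame(
  resid = c("ARG", "ASN", "LYS"),
  resno = c(515L, 519L, 520L),
  zoff = c(0, 10, 20))

#' Toy receptor fixture
#'
#' A synthetic three-residue polypeptide fragment (ARG-515, ASN-519,
#' LYS-520 on chain A, residues spaced 10 Angstrom apart) generated
#' programmatically with idealized side-chain geometry; the residue
#' numbers match the contact labels of the docking analysis.
#'
#' @param file output PDB path (default: a tempfile).
#' @return the path, invisibly carrying the PDB text as attribute
#'   `"text"`.
#' @export
toy_receptor <- function(file = tempfile(fileext = ".pdb")) {
  lines <- c("HEADER    SYNTHETIC RECEPTOR FIXTURE")
  serial <- 0L
  for (k in seq_len(nrow(.TOY_LAYOUT))) {
    res <- .TOY_LAYOUT$resid[k]
    tpl <- .RESIDUE_TEMPLATES[[res]]
    for (a in rownames(tpl)) {
      serial <- serial + 1L
      xyz <- tpl[a, ] + c(0, 0, .TOY_LAYOUT$zoff[k])
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, a, res, .TOY_LAYOUT$resno[k], xyz[1], xyz[2], xyz[3],
        substr(a, 1L, 1L)))
    }
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, file)
  attr(file, "text") <- lines
  invisible(file)
}

# Position of a named atom of the toy receptor, in receptor coordinates.
.toy_atom_xyz <- function(resno, atom) {
  k <- match(resno, .TOY_LAYOUT$resno)
  tpl <- .RESIDUE_TEMPLATES[[.TOY_LAYOUT$resid[k]]]
  tpl[atom, ] + c(0, 0, .TOY_LAYOUT$zoff[k])
}

#' Probe ligand pose at a controlled hydrogen-bond distance
#'
#' A methanol probe whose hydroxyl oxygen sits exactly `distance`
#' Angstrom from the ASN-519 side-chain oxygen (OD1) of the toy receptor,
#' approached along the CG-OD1 direction so no other polar receptor atom
#' is within hydrogen-bond range; the hydroxyl hydrogen points at the
#' acceptor.  Built by construction for contact-detection tests.
#'
#' @param distance donor-acceptor distance in Angstrom.
#' @return a `docking_pose`-shaped list (`xyz`, `elem`, `mol`).
#' @export
toy_probe_pose <- function(distance = 1.9) {
  od1 <- .toy_atom_xyz(519L, "OD1")
  cg <- .toy_atom_xyz(519L, "CG")
  u <- (od1 - cg) / sqrt(sum((od1 - cg)^2))
  o <- od1 + distance * u
  c1 <- o + 1.43 * u
  h <- o - 0.96 * u
  structure(list(xyz = rbind(c1, o, h), elem = c("C", "O", "H"),
                 mol = parse_smiles("CO"), energy = NA_real_,
                 rank = 1L, engine = "fixture"),
            class = "docking_pose")
}

#' Mock docking-engine report
#'
#' Syntactically valid report text in both supported dialects (the
#' Vina-style result table and AutoDock DLG energy records) embedding the
#' given energies.
#'
#' @param n_poses number of poses.
#' @param energies numeric vector of length `n_poses` (kcal/mol).
#' @return list with elements `vina` and `dlg` (single strings).
#' @export
mock_engine_report <- function(n_poses, energies) {
  if (n_poses < 1L) stop("n_poses must be >= 1", call. = FALSE)
  if (length(energies) != n_poses)
    stop("energies must have length n_poses", call. = FALSE)
  vina <- c(
    "mode |   affinity | dist from best mode",
    "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
    "-----+------------+----------+----------",
    sprintf("%4d %12.2f %10.3f %10.3f", seq_len(n_poses), energies,
            0, 0))
  dlg <- as.vector(rbind(
    sprintf("DOCKED: MODEL %8d", seq_len(n_poses)),
    sprintf("DOCKED: USER    Estimated Free Energy of Binding    =%+8.2f kcal/mol",
            energies),
    rep("DOCKED: ENDMDL", n_poses)))
  list(vina = paste(vina, collapse = "\n"),
       dlg = paste(dlg, collapse = "\n"))
}

#' Seeded smoke-scale pipeline configuration
#'
#' A desk-scale configuration exercising every stage end-to-end in a few
#' minutes on one CPU: 200 episodes of at most 8 edits with the
#' deterministic surrogate affinity oracle and a compact Q-network, fully
#' reproducible from its fixed master seed.  The epsilon schedule mirrors
#' the full study's convention (decrement = 1/episodes).
#'
#' @param seed master seed.
#' @return list with components `lead`, `mdp`, `agent`, `reward`,
#'   `thresholds`, `box`.
#' @export
seeded_smoke_config <- function(seed = 20240305L) {
  list(lead = lead_structure(),
       mdp = mdp_config(step_limit = 8L),
       agent = agent_config(episodes = 200L,
                            fp_width = 256L, hidden = c(128L, 64L),
                            replay_capacity = 2000L, batch_size = 32L,
                            target_sync_every = 10L,
                            learning_rate = 1e-3, seed = seed),
       reward = reward_config(),
       thresholds = screening_thresholds(),
       box = build_grid_box(c(80L, 60L, 60L), 0.375,
                            c(23.895, 49.094, 134.275)))
}
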