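# Docking validation stage: grid-box construction, receptor and ligand
# preparation, engine invocation (through an adapter so that mock reports
# and real engines share one parsing path), pose handling and
# hydrogen-bond contact analysis.

#' Docking grid box
#'
#' @param npts integer length-3: grid points per axis.
#' @param spacing grid spacing in Angstrom.
#' @param center numeric length-3 center in the receptor frame (Angstrom).
#' @return an object of class `grid_box` with derived physical `extent`
#'   (npts * spacing per axis).
#' @examples
#' build_grid_box(c(80, 60, 60), 0.375, c(23.895, 49.094, 134.275))
#' @export
build_grid_box <- function(npts, spacing, center) {
  if (length(npts) != 3L || any(!is.finite(npts)) || any(npts < 2L))
    stop("npts must be three integers >= 2", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a positive number", call. = FALSE)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("center must be a finite numeric triple", call. = FALSE)
  structure(list(npts = as.integer(npts), spacing = spacing,
                 center = as.numeric(center),
                 extent = as.integer(npts) * spacing),
            class = "grid_box")
}

#' @export
print.grid_box <- function(x, ...) {
  cat(sprintf("<grid_box: %d x %d x %d pts, %.3f A spacing, center (%.3f, %.3f, %.3f), extent %.1f x %.1f x %.1f A>\n",
              x$npts[1], x$npts[2], x$npts[3], x$spacing,
              x$center[1], x$center[2], x$center[3],
              x$extent[1], x$extent[2], x$extent[3]))
  invisible(x)
}

#' Grid parameters in the engine's native dialect
#'
#' The `npts` / `spacing` / `gridcenter` lines of an AutoGrid parameter
#' file, field-exact.
#'
#' @param box a `grid_box`.
#' @return character vector of parameter lines.
#' @export
grid_parameter_lines <- function(box) {
  c(sprintf("npts %d %d %d", box$npts[1], box$npts[2], box$npts[3]),
    sprintf("spacing %.3f", box$spacing),
    sprintf("gridcenter %.3f %.3f %.3f",
            box$center[1], box$center[2], box$center[3]))
}

#' Prepare a receptor structure for docking
#'
#' Reads a PDB file, strips waters, reports (never silently repairs)
#' missing pieces, warns on nonstandard residue codes and writes the
#' cleaned structure with residue numbering preserved.
#'
#' @param pdb_file input PDB path.
#' @param out_file optional output path (default: tempfile).
#' @return invisibly, a list with the `bio3d` pdb object (`pdb`) and the
#'   written `path`.
#' @export
prepare_receptor <- function(pdb_file, out_file = NULL) {
  if (!file.exists(pdb_file)) stop("no such file: ", pdb_file,
                                   call. = FALSE)
  pdb <- bio3d::read.pdb(pdb_file, verbose = FALSE)
  atoms <- pdb$atom
  if (!nrow(atoms)) stop("PDB contains no atoms", call. = FALSE)
  water <- atoms$resid %in% c("HOH", "WAT", "DOD", "H2O")
  atoms <- atoms[!water, , drop = FALSE]
  standard <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                "THR", "TRP", "TYR", "VAL")
  odd <- setdiff(unique(atoms$resid), standard)
  if (length(odd))
    warning("nonstandard residue code(s) passed through: ",
            paste(odd, collapse = ", "), call. = FALSE)
  if (is.null(out_file)) out_file <- tempfile(fileext = ".pdb")
  pdb2 <- pdb
  pdb2$atom <- atoms
  pdb2$xyz <- as.numeric(t(atoms[, c("x", "y", "z")]))
  bio3d::write.pdb(pdb2, file = out_file)
  invisible(list(pdb = pdb2, path = out_file))
}

# --- engine adapter ---------------------------------------------------------

#' Docking engine configuration
#'
#' `mock` replays deterministic reports through the same parser used for
#' real engine output; `vina` and `autodock4` build command lines for the
#' respective binaries (paths supplied by the caller).
#'
#' @param engine `"mock"`, `"vina"` or `"autodock4"`.
#' @param command binary path for real engines.
#' @param seed engine seed flag value, where supported.
#' @param runner optional function
#'   `(conformer, receptor_path, box, n_poses) -> report text`, overriding
#'   the built-in invocation (the mock fixture supplies one).
#' @return an object of class `engine_config`.
#' @export
engine_config <- function(engine = c("mock", "vina", "autodock4"),
                          command = NULL, seed = NULL, runner = NULL) {
  engine <- match.arg(engine)
  if (engine != "mock" && is.null(command) && is.null(runner))
    stop("engine '", engine, "' needs a command path (binary not ",
         "configured)", call. = FALSE)
  structure(list(engine = engine, command = command, seed = seed,
                 runner = runner),
            class = "engine_config")
}

#' Parse a Vina-style result table
#'
#' @param text report text (character vector or single string).
#' @return data.frame with `rank` (as reported) and `energy` (kcal/mol).
#' @export
parse_vina_report <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  hits <- grep("^\\s*\\d+\\s+-?\\d+(\\.\\d+)?\\s+", lines, value = TRUE)
  if (!length(hits))
    stop("no pose table found in Vina-style report", call. = FALSE)
  toks <- lapply(strsplit(trimws(hits), "\\s+"), as.numeric)
  data.frame(rank = vapply(toks, `[`, 0, 1L),
             energy = vapply(toks, `[`, 0, 2L))
}

#' Parse an AutoDock DLG report
#'
#' Extracts the per-pose estimated free energies of binding, in report
#' order.
#'
#' @param text report text.
#' @return data.frame with `rank` and `energy` (kcal/mol).
#' @export
parse_dlg_report <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  hits <- grep("Estimated Free Energy of Binding", lines, value = TRUE)
  if (!length(hits))
    stop("no binding-energy records found in DLG report", call. = FALSE)
  energy <- as.numeric(sub(".*=\\s*(-?\\d+(\\.\\d+)?).*", "\\1", hits))
  data.frame(rank = seq_along(energy), energy = energy)
}

.parse_engine_report <- function(text) {
  joined <- paste(unlist(strsplit(text, "\n", fixed = TRUE)),
                  collapse = "\n")
  if (grepl("DOCKED:", joined, fixed = TRUE) ||
      grepl("Estimated Free Energy of Binding", joined, fixed = TRUE))
    parse_dlg_report(joined)
  else parse_vina_report(joined)
}

#' Dock a ligand and return energy-sorted poses
#'
#' Embeds the ligand, invokes the configured engine (or mock runner) for
#' up to `poses` binding poses and returns them sorted by energy,
#' preserving report order among exact ties.
#'
#' @param ligand a `molecule`.
#' @param receptor path to the prepared receptor file.
#' @param box a `grid_box`.
#' @param poses number of binding poses requested (study setting 20).
#' @param engine an `engine_config`.
#' @return list of `docking_pose` objects (fields `xyz`, `elem`, `energy`,
#'   `rank`, `engine`).
#' @export
dock <- function(ligand, receptor, box, poses = 20L,
                 engine = engine_config("mock")) {
  conf <- embed_3d(ligand)
  runner <- engine$runner
  if (is.null(runner)) {
    if (engine$engine == "mock")
      runner <- .default_mock_runner
    else
      runner <- .external_engine_runner
  }
  report <- runner(conf, receptor, box, poses, engine)
  tab <- .parse_engine_report(report)
  if (nrow(tab) > poses) tab <- tab[seq_len(poses), , drop = FALSE]
  if (nrow(tab) < poses)
    warning("engine returned ", nrow(tab), " pose(s) of ", poses,
            " requested", call. = FALSE)
  ord <- order(tab$energy)            # stable: ties keep report order
  tab <- tab[ord, , drop = FALSE]
  # mock poses reuse the embedded conformer translated to the box center
  shift <- box$center - colMeans(conf$xyz)
  xyz <- sweep(conf$xyz, 2L, shift, `+`)
  lapply(seq_len(nrow(tab)), function(i)
    structure(list(xyz = xyz, elem = conf$elem, mol = ligand,
                   energy = tab$energy[i], rank = i,
                   engine = engine$engine),
              class = "docking_pose"))
}

.default_mock_runner <- function(conf, receptor, box, poses, engine) {
  # deterministic energies anchored at the surrogate affinity
  base <- surrogate_affinity(conf$mol)
  energies <- round(base + 0.35 * (seq_len(poses) - 1L), 2)
  mock_engine_report(poses, energies)$vina
}

.external_engine_runner <- function(conf, receptor, box, poses, engine) {
  lig <- tempfile(fileext = ".sdf"); out <- tempfile(fileext = ".txt")
  on.exit(unlink(c(lig, out, paste0(lig, ".pdbqt"))))
  write_conformer_sdf(conf, lig)
  suppressWarnings(system2("obabel", c(lig, "-opdbqt", "-O",
                                       paste0(lig, ".pdbqt")),
                           stdout = FALSE, stderr = FALSE))
  args <- c("--receptor", receptor, "--ligand", paste0(lig, ".pdbqt"),
            "--center_x", box$center[1], "--center_y", box$center[2],
            "--center_z", box$center[3],
            "--size_x", box$extent[1], "--size_y", box$extent[2],
            "--size_z", box$extent[3], "--num_modes", poses)
  if (!is.null(engine$seed)) args <- c(args, "--seed", engine$seed)
  res <- suppressWarnings(system2(engine$command, args, stdout = TRUE,
                                  stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L)
    stop("docking engine failed (exit ", status, "):\n",
         paste(utils::tail(res, 20L), collapse = "\n"), call. = FALSE)
  paste(res, collapse = "\n")
}

#' Best docking energy of a molecule (cached)
#'
#' The lowest predicted binding free energy over the engine's poses,
#' cached by canonical SMILES so that repeated reward queries do not
#' re-invoke the engine.
#'
#' @inheritParams dock
#' @return energy in kcal/mol.
#' @export
docking_affinity <- function(ligand, receptor, box, poses = 20L,
                             engine = engine_config("mock")) {
  key <- paste0("dock:", to_canonical_smiles(ligand))
  hit <- .reward_cache[[key]]
  if (!is.null(hit)) return(hit)
  ps <- dock(ligand, receptor, box, poses, engine)
  val <- ps[[1L]]$energy
  .reward_cache[[key]] <- val
  val
}

# --- hydrogen-bond contacts -------------------------------------------------

#' Hydrogen-bond geometry criteria
#'
#' Donor-acceptor heavy-atom distance cutoff with distance-classed
#' strength bins: strong <= `strong_max` < moderate <= `cutoff`, weak
#' beyond (only reported if the cutoff is raised).  When the donor's
#' hydrogen position is known, a donor-H...acceptor angle criterion is
#' applied as well; receptor structures without hydrogens are assessed by
#' distance only.
#'
#' @param cutoff maximum donor-acceptor distance (Angstrom).
#' @param strong_max upper bound of the "strong" class (Angstrom).
#' @param angle_min minimum donor-H-acceptor angle in degrees.
#' @return an object of class `hbond_config`.
#' @export
hbond_config <- function(cutoff = 3.5, strong_max = 2.5, angle_min = 120) {
  structure(list(cutoff = cutoff, strong_max = strong_max,
                 angle_min = angle_min),
            class = "hbond_config")
}

.hbond_class <- function(d, cfg) {
  ifelse(d <= cfg$strong_max, "strong",
         ifelse(d <= 3.5, "moderate", "weak"))
}

#' Detect hydrogen-bond contacts between a pose and the receptor
#'
#' All ligand-receptor donor/acceptor N,O pairs within the distance
#' cutoff.  Ligand donors are N/O atoms carrying hydrogens; receptor
#' nitrogens are treated as donor-capable and receptor oxygens as
#' acceptors (side-chain hydroxyls as both).  Residues are reported as
#' NAME-number.
#'
#' @param pose a `docking_pose` (or any list with `xyz`, `elem`, `mol`).
#' @param receptor a `bio3d` pdb object or PDB path.
#' @param cfg an `hbond_config`.
#' @param box optional `grid_box` for a frame-consistency check.
#' @return data.frame of contacts: donor/acceptor owner and label,
#'   residue, distance (Angstrom), class.
#' @export
detect_hbonds <- function(pose, receptor, cfg = hbond_config(),
                          box = NULL) {
  if (is.character(receptor))
    receptor <- bio3d::read.pdb(receptor, verbose = FALSE)
  ra <- receptor$atom
  ra <- ra[!ra$resid %in% c("HOH", "WAT"), , drop = FALSE]
  relem <- ifelse(!is.na(ra$elesy) & nzchar(ra$elesy), ra$elesy,
                  substr(trimws(ra$elety), 1L, 1L))
  rpolar <- which(relem %in% c("N", "O"))
  if (!length(rpolar)) return(.empty_contacts())
  rxyz <- as.matrix(ra[rpolar, c("x", "y", "z")])
  rlabel <- paste0(ra$resid[rpolar], "-", ra$resno[rpolar])
  ratom <- trimws(ra$elety[rpolar])
  rdonor <- relem[rpolar] == "N" |
    (relem[rpolar] == "O" & ratom %in% c("OG", "OG1", "OH"))
  raccept <- relem[rpolar] %in% c("N", "O")

  m <- pose$mol
  heavy <- which(pose$elem != "H")
  lelem <- pose$elem[heavy]
  lpolar <- which(lelem %in% c("N", "O"))
  if (!length(lpolar)) return(.empty_contacts())
  lxyz <- pose$xyz[heavy[lpolar], , drop = FALSE]
  ldonor <- m$nH[lpolar] > 0L
  laccept <- rep(TRUE, length(lpolar))
  lgroup <- paste0(lelem[lpolar],
                   ifelse(m$nH[lpolar] > 0L, "H", ""))

  if (!is.null(box)) {
    centroid <- colMeans(pose$xyz)
    if (sqrt(sum((centroid - box$center)^2)) >
        sqrt(sum((box$extent / 2)^2)))
      warning("ligand centroid lies outside the grid box: possible ",
              "coordinate-frame mismatch", call. = FALSE)
  }

  # explicit ligand hydrogens, for the angle criterion
  hxyz <- pose$xyz[pose$elem == "H", , drop = FALSE]

  out <- list()
  for (i in seq_along(lpolar)) {
    for (j in seq_along(rpolar)) {
      d <- sqrt(sum((lxyz[i, ] - rxyz[j, ])^2))
      if (d > cfg$cutoff || d <= 0) next
      lig_don <- ldonor[i] && raccept[j]
      rec_don <- rdonor[j] && laccept[i]
      if (!lig_don && !rec_don) next
      if (lig_don && nrow(hxyz)) {
        # angle criterion over the donor's hydrogens
        hd <- sqrt(rowSums(sweep(hxyz, 2L, lxyz[i, ])^2))
        near <- which(hd < 1.3)
        if (length(near)) {
          ang <- vapply(near, function(h) {
            v1 <- lxyz[i, ] - hxyz[h, ]; v2 <- rxyz[j, ] - hxyz[h, ]
            acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
          }, 0)
          lig_don <- any(ang >= cfg$angle_min)
          if (!lig_don && !rec_don) next
        }
      }
      don_owner <- if (lig_don) "ligand" else "receptor"
      out[[length(out) + 1L]] <- data.frame(
        donor_owner = don_owner,
        donor_label = if (lig_don) lgroup[i] else
          paste0(rlabel[j], ":", ratom[j]),
        acceptor_owner = if (lig_don) "receptor" else "ligand",
        acceptor_label = if (lig_don) paste0(rlabel[j], ":", ratom[j])
          else lgroup[i],
        residue = rlabel[j],
        distance = d,
        class = .hbond_class(d, cfg),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_contacts())
  res <- do.call(rbind, out)
  res <- res[order(res$distance), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_contacts <- function() {
  data.frame(donor_owner = character(0), donor_label = character(0),
             acceptor_owner = character(0), acceptor_label = character(0),
             residue = character(0), distance = numeric(0),
             class = character(0), stringsAsFactors = FALSE)
}
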