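# 3-D structure generation (OpenBabel builder).

#' Embed a molecule in 3-D
#'
#' Generates a single low-energy conformer by a fully deterministic
#' OpenBabel route: the (deterministic) 2-D structure layout is lifted to
#' 3-D with a seeded out-of-plane jitter, hydrogens are made explicit,
#' and the geometry is relaxed by steepest-descent forcefield
#' minimization (MMFF94 with a UFF fallback), which is deterministic for
#' a fixed starting geometry.  The same molecule and seed therefore give
#' bitwise-identical coordinates; different seeds explore different
#' torsional basins.
#'
#' @param m a valid, connected `molecule`.
#' @param seed integer controlling the out-of-plane jitter.
#' @return an object of class `conformer`: fields `mol`, `elem` (per
#'   atom, hydrogens expanded), `xyz` (matrix, Angstrom), bond arrays
#'   including hydrogens, `seed`.
#' @export
embed_3d <- function(m, seed = 0L) {
  v <- validate_molecule(m)
  if (!isTRUE(v)) stop("cannot embed invalid molecule: ", v, call. = FALSE)
  if (!is_connected(m))
    stop("cannot embed a disconnected molecule (",
         to_canonical_smiles(m), ")", call. = FALSE)
  fin <- tempfile(fileext = ".mol"); f2d <- tempfile(fileext = ".sdf")
  f3s <- tempfile(fileext = ".mol"); fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, f2d, f3s, fout)))
  writeLines(write_molblock(m), fin)
  suppressWarnings(system2("obabel", c(fin, "-osdf", "-O", f2d,
                                       "--gen2d"),
                           stdout = FALSE, stderr = FALSE))
  lines2d <- if (file.exists(f2d)) readLines(f2d) else character(0)
  if (length(lines2d) < 5L)
    stop("2-D layout failed for ", to_canonical_smiles(m), call. = FALSE)
  blk2d <- .parse_molblock(lines2d)
  n <- length(blk2d$elem)
  # seeded out-of-plane jitter breaks planarity before minimization
  rs <- .Random.seed_save()
  set.seed(as.integer(seed) + 1139L)
  z <- stats::runif(n, -0.45, 0.45)
  .Random.seed_restore(rs)
  xyz0 <- cbind(blk2d$xyz[, 1:2, drop = FALSE], z)
  addh <- "-h"
  if (n == 1L) {
    # hydrogen directions on an isolated atom are not geometrically
    # determined; place them from a tetrahedral template instead
    tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                 c(-1, -1, 1)) / sqrt(3)
    k <- m$nH[1L]
    if (k > 0L) {
      hl <- c(C = 1.09, N = 1.01, O = 0.96)[m$elem[1L]]
      if (is.na(hl)) hl <- 1.05
      hxyz <- sweep(tet[seq_len(k), , drop = FALSE] * hl, 2L,
                    xyz0[1L, ], `+`)
      mh <- new_molecule(c(m$elem, rep("H", k)),
                         c(m$charge, integer(k)), integer(1L + k),
                         rep(1L, k), 1L + seq_len(k), rep(1L, k),
                         logical(k), logical(1L + k))
      writeLines(write_molblock(mh, coords = rbind(xyz0, hxyz)), f3s)
      addh <- NULL
    } else writeLines(write_molblock(m, coords = xyz0), f3s)
  } else {
    writeLines(write_molblock(m, coords = xyz0), f3s)
  }
  for (ff in c("mmff94", "uff")) {
    suppressWarnings(system2("obabel",
                             c(f3s, "-osdf", "-O", fout, addh,
                               "--minimize", "--ff", ff, "--sd",
                               "--steps", "600"),
                             stdout = FALSE, stderr = FALSE))
    lines <- if (file.exists(fout)) readLines(fout) else character(0)
    if (length(lines) >= 5L) {
      blk <- .parse_molblock(lines)
      if (!anyNA(blk$xyz) && !all(abs(blk$xyz) < 1e-8)) {
        return(structure(list(mol = m, elem = blk$elem, xyz = blk$xyz,
                              from = blk$from, to = blk$to,
                              order = blk$order, seed = as.integer(seed)),
                         class = "conformer"))
      }
    }
  }
  stop("3-D embedding failed for ", to_canonical_smiles(m), call. = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(rs) {
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer: %d atoms (H expanded), seed %d>\n",
              nrow(x$xyz), x$seed))
  invisible(x)
}

#' Write a conformer as an SD file
#' @param conf a `conformer`.
#' @param file output path.
#' @export
write_conformer_sdf <- function(conf, file) {
  hdr <- c("", " leadopt", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   length(conf$elem), length(conf$from)))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                conf$xyz[, 1L], conf$xyz[, 2L], conf$xyz[, 3L], conf$elem)
  bl <- sprintf("%3d%3d%3d  0  0  0  0", conf$from, conf$to, conf$order)
  writeLines(c(hdr, at, bl, "M  END", "$$$$"), file)
  invisible(file)
}
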