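# Editable molecular graph with valence bookkeeping.
#
# A `molecule` is a plain list so that the action enumerator can copy and
# edit it cheaply inside the RL loop:
#   elem    character(n)  element symbols, dense 1-based indexing
#   charge  integer(n)    formal charges
#   nH      integer(n)    implicit hydrogens == free valence (see below)
#   from,to integer(m)    bond endpoints, from < to
#   order   integer(m)    kekule bond order 1/2/3
#   arom    logical(m)    perceived-aromatic flag (frozen bonds)
#   arom_atom logical(n)  atom sits in an aromatic ring
#
# Valence convention: bookkeeping uses kekule orders, not fractional
# aromatic orders, so that sums stay integral for five-membered
# heteroaromatics (a pyrrole-type nitrogen has bond sum 3, not 4).
# Implicit hydrogens are replaceable, so an atom's free valence equals its
# implicit-hydrogen count; a benzene carbon therefore has free valence 1
# and can accept a substituent, as in the MolDQN action space.

#' Permitted valences for the neutral element set
#'
#' Heavy-atom valences used for validation and free-valence accounting.
#' The editable set is {C, N, O}; the remaining entries cover elements that
#' may appear when parsing arbitrary input SMILES.
#' @keywords internal
PERMITTED_VALENCE <- c(
  C = 4L, N = 3L, O = 2L, F = 1L, Cl = 1L, Br = 1L, I = 1L,
  B = 3L, P = 3L, S = 2L, Si = 4L
)

# Elements whose valence may legitimately exceed the table (hypervalent).
.MULTIVALENT <- list(S = c(2L, 4L, 6L), P = c(3L, 5L))

new_molecule <- function(elem, charge, nH, from, to, order, arom,
                         arom_atom) {
  structure(
    list(elem = as.character(elem), charge = as.integer(charge),
         nH = as.integer(nH), from = as.integer(from), to = as.integer(to),
         order = as.integer(order), arom = as.logical(arom),
         arom_atom = as.logical(arom_atom)),
    class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d heavy atoms, %d bonds, formula %s>\n",
              length(x$elem), length(x$from), mol_formula(x)))
  cat(" ", to_canonical_smiles(x), "\n")
  invisible(x)
}

mol_formula <- function(m) {
  tab <- table(m$elem)
  nh <- sum(m$nH)
  ord <- c(intersect(c("C", "N", "O"), names(tab)),
           setdiff(sort(names(tab)), c("C", "N", "O")))
  parts <- vapply(ord, function(e)
    paste0(e, if (tab[[e]] > 1L) tab[[e]] else ""), "")
  paste0(paste(parts, collapse = ""), if (nh > 0) paste0("H", nh) else "")
}

n_atoms <- function(m) length(m$elem)
n_bonds <- function(m) length(m$from)

# --- OpenBabel bridge -------------------------------------------------------

ob_convert <- function(from, to, text, opts = NULL) {
  if (is.null(opts))
    suppressWarnings(ChemmineOB::convertFormat(from, to, text))
  else
    suppressWarnings(ChemmineOB::convertFormat(from, to, text,
                                               options = opts))
}

gen2d_opts <- function() data.frame(names = "gen2D", args = "")

# Parse the atom/bond blocks of a single V2000 molblock (SDF record).
# Explicit hydrogens are folded into the nH counts of their heavy neighbor.
.parse_molblock <- function(lines) {
  if (length(lines) < 4L) stop("truncated molblock", call. = FALSE)
  counts <- lines[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(na) || is.na(nb)) stop("malformed molblock counts line",
                                   call. = FALSE)
  at <- lines[4L + seq_len(na)]
  elem <- trimws(substr(at, 32L, 34L))
  xyz <- cbind(as.numeric(substr(at, 1L, 10L)),
               as.numeric(substr(at, 11L, 20L)),
               as.numeric(substr(at, 21L, 30L)))
  bl <- if (nb > 0L) lines[4L + na + seq_len(nb)] else character(0)
  bfrom <- as.integer(substr(bl, 1L, 3L))
  bto <- as.integer(substr(bl, 4L, 6L))
  border <- as.integer(substr(bl, 7L, 9L))
  charge <- integer(na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)),
                                "\\s+")[[1]])
    k <- toks[1L]
    idx <- toks[1L + 2L * seq_len(k) - 1L]
    chg <- toks[1L + 2L * seq_len(k)]
    charge[idx] <- chg
  }
  list(elem = elem, charge = charge, xyz = xyz,
       from = bfrom, to = bto, order = border)
}

# Fold explicit H atoms into implicit counts and reindex heavy atoms.
.fold_hydrogens <- function(blk) {
  heavy <- blk$elem != "H"
  map <- cumsum(heavy)          # old index -> new heavy index (H -> junk)
  nH <- integer(sum(heavy))
  keep <- logical(length(blk$from))
  for (k in seq_along(blk$from)) {
    f <- blk$from[k]; t <- blk$to[k]
    fh <- !heavy[f]; th <- !heavy[t]
    if (fh && th) { keep[k] <- FALSE; next }          # H-H: drop
    if (fh || th) {
      hv <- if (fh) t else f
      nH[map[hv]] <- nH[map[hv]] + 1L
      keep[k] <- FALSE
    } else keep[k] <- TRUE
  }
  from <- map[blk$from[keep]]; to <- map[blk$to[keep]]
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  list(elem = blk$elem[heavy], charge = blk$charge[heavy], nH = nH,
       from = from, to = to, order = blk$order[keep])
}

# Aromatic bond flags for the heavy-atom graph of a SMILES string, read from
# OpenBabel's MOL2 output (bond type "ar").  Heavy-atom order matches the
# SDF conversion of the same string.
.aromatic_flags <- function(smiles, n, from, to) {
  m2 <- ob_convert("SMI", "MOL2", smiles)
  ln <- strsplit(m2, "\n", fixed = TRUE)[[1]]
  ai <- grep("@<TRIPOS>ATOM", ln, fixed = TRUE)[1]
  bi <- grep("@<TRIPOS>BOND", ln, fixed = TRUE)[1]
  ei <- c(grep("@<TRIPOS>", ln, fixed = TRUE), length(ln) + 1L)
  bend <- min(ei[ei > bi]) - 1L
  arom <- logical(length(from))
  if (is.na(bi) || bend < bi + 1L) return(arom)
  key <- paste(from, to)
  for (row in ln[(bi + 1L):bend]) {
    tk <- strsplit(trimws(row), "\\s+")[[1]]
    if (length(tk) < 4L) next
    a <- as.integer(tk[2L]); b <- as.integer(tk[3L])
    if (is.na(a) || is.na(b) || a > n || b > n || tk[4L] != "ar") next
    k <- match(paste(min(a, b), max(a, b)), key)
    if (!is.na(k)) arom[k] <- TRUE
  }
  arom
}

#' Parse a SMILES string into an editable molecule
#'
#' Delegates ring/aromaticity perception and the hydrogen model to
#' OpenBabel, then builds the package's editable graph with kekule bond
#' orders and implicit-hydrogen (free-valence) bookkeeping.  Aromatic bonds
#' are flagged and later treated as frozen by the action enumerator.
#'
#' @param text a single non-empty SMILES string.
#' @return an object of class `molecule`.
#' @examples
#' m <- parse_smiles("c1ccccc1")  # benzene
#' free_valence(m, 1)             # 1: the ring CH can accept a substituent
#' @export
parse_smiles <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("SMILES input must be a single non-empty string", call. = FALSE)
  text <- trimws(text)
  sdf <- tryCatch(ob_convert("SMI", "SDF", text,
                             opts = data.frame(names = "h", args = "")),
                  error = function(e) "")
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 5L || !any(grepl("V2000", lines)))
    stop(.smiles_diagnostic(text), call. = FALSE)
  blk <- .parse_molblock(lines)
  g <- .fold_hydrogens(blk)
  if (length(g$elem) == 0L)
    stop("SMILES '", text, "' contains no heavy atoms", call. = FALSE)
  arom <- .aromatic_flags(text, length(g$elem), g$from, g$to)
  arom_atom <- logical(length(g$elem))
  arom_atom[c(g$from[arom], g$to[arom])] <- TRUE
  m <- new_molecule(g$elem, g$charge, g$nH, g$from, g$to, g$order, arom,
                    arom_atom)
  v <- validate_molecule(m)
  if (!isTRUE(v))
    stop("valence-invalid SMILES '", text, "': ", v, call. = FALSE)
  attr(m, "cansmi") <- .ob_cansmi_text(text, "SMI")
  m
}

# Point at the offending token where cheaply possible.
.smiles_diagnostic <- function(text) {
  bad <- regmatches(text, regexpr("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\%.*]",
                                  text, perl = TRUE))
  if (length(bad) && nzchar(bad))
    return(paste0("cannot parse SMILES '", text,
                  "': unexpected token '", bad, "'"))
  open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (open != close)
    return(paste0("cannot parse SMILES '", text,
                  "': unbalanced parentheses"))
  paste0("cannot parse SMILES '", text, "'")
}

.ob_cansmi_text <- function(text, fmt) {
  out <- tryCatch(ob_convert(fmt, "CAN", text), error = function(e) "")
  out <- trimws(strsplit(out, "\n", fixed = TRUE)[[1]])
  out <- out[nzchar(out)]
  if (!length(out)) {
    # in-process converter throws on rare polycyclic cages; CLI route
    tf <- tempfile(fileext = paste0(".", tolower(fmt)))
    on.exit(unlink(tf))
    writeLines(text, tf)
    out <- suppressWarnings(system2("obabel", c(tf, "-ocan"),
                                    stdout = TRUE, stderr = FALSE))
    out <- trimws(out); out <- out[nzchar(out)]
    if (!length(out)) stop("canonicalization failed", call. = FALSE)
  }
  sub("\t.*$", "", out)
}

#' Validate the valence bookkeeping of a molecule
#'
#' Checks that every neutral atom of a tabulated element satisfies
#' bond-order sum + implicit hydrogens == a permitted valence, and that the
#' graph arrays are structurally consistent.
#'
#' @param m a `molecule`.
#' @return `TRUE`, or a character description of the first violation.
#' @export
validate_molecule <- function(m) {
  n <- n_atoms(m)
  if (n == 0L) return("empty molecule")
  if (length(m$from) != length(m$to) || length(m$from) != length(m$order))
    return("ragged bond arrays")
  if (n_bonds(m) > 0L) {
    if (any(m$from < 1L | m$to > n | m$from >= m$to))
      return("bond endpoint out of range")
    if (anyDuplicated(paste(m$from, m$to)))
      return("duplicate bond")
    if (any(!(m$order %in% 1:3)))
      return("bond order outside {1,2,3}")
  }
  if (any(m$nH < 0L)) return("negative implicit-hydrogen count")
  bsum <- bond_order_sums(m)
  for (i in seq_len(n)) {
    if (m$charge[i] != 0L) next       # charged atoms follow the parser's model
    e <- m$elem[i]
    perm <- PERMITTED_VALENCE[e]
    if (is.na(perm)) next
    tot <- bsum[i] + m$nH[i]
    ok <- if (e %in% names(.MULTIVALENT)) tot %in% .MULTIVALENT[[e]]
          else tot == perm
    if (!ok)
      return(sprintf("atom %d (%s): bond sum %d + %dH != permitted valence",
                     i, e, bsum[i], m$nH[i]))
  }
  TRUE
}

bond_order_sums <- function(m) {
  n <- n_atoms(m)
  s <- integer(n)
  if (n_bonds(m) > 0L) {
    agg <- rowsum(c(m$order, m$order), c(m$from, m$to))
    s[as.integer(rownames(agg))] <- as.integer(agg[, 1L])
  }
  s
}

#' Free valence of an atom
#'
#' The number of additional bond orders the atom can accept, i.e. its
#' implicit-hydrogen count under the package's convention that implicit
#' hydrogens are replaceable (a methane carbon has free valence 4, a
#' benzene carbon 1, a hydroxyl oxygen 1).
#'
#' @param m a `molecule`.
#' @param i 1-based atom index.
#' @return non-negative integer.
#' @export
free_valence <- function(m, i) {
  if (!is.numeric(i) || length(i) != 1L || is.na(i) || i < 1L ||
      i > n_atoms(m))
    stop("atom index out of range: ", i, call. = FALSE)
  m$nH[as.integer(i)]
}

# --- serialization ----------------------------------------------------------

#' Write a molecule as a V2000 molblock
#' @param m a `molecule`.
#' @param coords optional numeric matrix (n x 3) of coordinates.
#' @return a single string ending in `M  END`.
#' @keywords internal
write_molblock <- function(m, coords = NULL) {
  n <- n_atoms(m); b <- n_bonds(m)
  if (is.null(coords)) coords <- matrix(0, n, 3L)
  hdr <- c("", " leadopt", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, b))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                coords[, 1L], coords[, 2L], coords[, 3L], m$elem)
  bl <- if (b > 0L) sprintf("%3d%3d%3d  0  0  0  0", m$from, m$to, m$order)
        else character(0)
  chg <- which(m$charge != 0L)
  cl <- if (length(chg))
    vapply(chg, function(i) sprintf("M  CHG  1 %3d %3d", i, m$charge[i]), "")
  else character(0)
  paste(c(hdr, at, bl, cl, "M  END"), collapse = "\n")
}

#' Canonical SMILES of a molecule
#'
#' OpenBabel canonical serialization; invariant under atom-index
#' permutations.  The string produced when the molecule was first parsed
#' (which preserves any stereo descriptors of the input) is cached; edited
#' molecules are serialized stereo-agnostically from their graph.
#'
#' @param m a `molecule`.
#' @return a SMILES string.
#' @export
to_canonical_smiles <- function(m) {
  cs <- attr(m, "cansmi")
  if (!is.null(cs)) return(cs)
  canonical_smiles(list(m))[[1L]]
}

#' Canonical SMILES for a list of molecules (batched)
#'
#' One OpenBabel invocation for the whole batch; markedly faster than
#' per-molecule calls inside the RL loop.
#'
#' @param mols list of `molecule` objects.
#' @return character vector of canonical SMILES.
#' @export
canonical_smiles <- function(mols) {
  if (!length(mols)) return(character(0))
  cached <- vapply(mols, function(m) {
    cs <- attr(m, "cansmi"); if (is.null(cs)) NA_character_ else cs
  }, "")
  todo <- which(is.na(cached))
  if (length(todo)) {
    sdf <- paste(vapply(mols[todo], write_molblock, ""),
                 collapse = "\n$$$$\n")
    sdf <- paste0(sdf, "\n$$$$\n")
    out <- tryCatch(.ob_cansmi_text(sdf, "SDF"), error = function(e)
      character(0))
    if (length(out) != length(todo)) {
      # a few polycyclic cages throw inside the in-process converter but
      # convert fine through the command-line tool; fall back per batch
      out <- .cli_cansmi(sdf, length(todo), mols[todo])
    }
    cached[todo] <- out
  }
  cached
}

# Command-line OpenBabel fallback; same engine and canonical strings as the
# in-process route.  Molecules the CLI also rejects get a stable
# non-SMILES placeholder key so that a long optimization run survives.
.cli_cansmi <- function(sdf, n_expected, mols) {
  tf <- tempfile(fileext = ".sdf"); on.exit(unlink(tf))
  writeLines(sdf, tf)
  out <- suppressWarnings(system2("obabel", c(tf, "-ocan"), stdout = TRUE,
                                  stderr = FALSE))
  out <- sub("\t.*$", "", trimws(out))
  out <- out[nzchar(out)]
  if (length(out) == n_expected) return(out)
  # identify survivors one by one
  res <- character(n_expected)
  for (i in seq_len(n_expected)) {
    ti <- tempfile(fileext = ".mol")
    writeLines(write_molblock(mols[[i]]), ti)
    oi <- suppressWarnings(system2("obabel", c(ti, "-ocan"), stdout = TRUE,
                                   stderr = FALSE))
    unlink(ti)
    oi <- sub("\t.*$", "", trimws(oi)); oi <- oi[nzchar(oi)]
    if (length(oi) == 1L) res[i] <- oi
    else {
      warning("canonicalization failed for one molecule; ",
              "using structural key placeholder", call. = FALSE)
      res[i] <- paste0("<uncanonicalizable:",
                       substr(mol_key(mols[[i]]), 1L, 40L), ">")
    }
  }
  res
}

# --- graph utilities --------------------------------------------------------

adjacency_list <- function(m) {
  n <- n_atoms(m)
  adj <- vector("list", n)
  if (n_bonds(m) > 0L) {
    ends <- c(m$from, m$to); nb <- c(m$to, m$from)
    sp <- split(nb, ends)
    adj[as.integer(names(sp))] <- sp
  }
  adj
}

# Connected-component labels (1-based) via BFS.
components <- function(m) {
  n <- n_atoms(m)
  adj <- adjacency_list(m)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur
        queue <- c(queue, w) }
    }
  }
  comp
}

is_connected <- function(m) n_atoms(m) <= 1L || max(components(m)) == 1L

# Ring membership per atom: an atom is in a ring iff it is incident to a
# bond lying on some cycle.  BFS spanning forest; every non-tree edge
# closes a fundamental cycle, whose tree path is marked via parent
# pointers.  The union of fundamental cycles is exactly the non-bridge
# edge set.
ring_membership <- function(m) {
  n <- n_atoms(m); b <- n_bonds(m)
  inring <- logical(n)
  if (b == 0L) return(inring)
  # CSR-style adjacency
  ends <- c(m$from, m$to); nb <- c(m$to, m$from)
  eid <- rep.int(seq_len(b), 2L)
  o <- order(ends)
  nb <- nb[o]; eid <- eid[o]
  deg <- tabulate(ends, n)
  ptr <- c(0L, cumsum(deg))
  parent <- integer(n); pedge <- integer(n); depth <- integer(n)
  visited <- logical(n)
  tree_edge <- logical(b); ring_edge <- logical(b)
  queue <- integer(n)
  for (root in seq_len(n)) {
    if (visited[root]) next
    visited[root] <- TRUE
    head_ <- 1L; tail_ <- 1L; queue[1L] <- root
    while (head_ <= tail_) {
      v <- queue[head_]; head_ <- head_ + 1L
      idx <- seq.int(ptr[v] + 1L, ptr[v + 1L])
      if (ptr[v] == ptr[v + 1L]) next
      for (ii in idx) {
        w <- nb[ii]; k <- eid[ii]
        if (!visited[w]) {
          visited[w] <- TRUE
          parent[w] <- v; pedge[w] <- k; depth[w] <- depth[v] + 1L
          tree_edge[k] <- TRUE
          tail_ <- tail_ + 1L; queue[tail_] <- w
        }
      }
    }
  }
  for (k in which(!tree_edge)) {
    u <- m$from[k]; v <- m$to[k]
    ring_edge[k] <- TRUE
    while (depth[u] > depth[v]) { ring_edge[pedge[u]] <- TRUE
      u <- parent[u] }
    while (depth[v] > depth[u]) { ring_edge[pedge[v]] <- TRUE
      v <- parent[v] }
    while (u != v) {
      ring_edge[pedge[u]] <- TRUE; u <- parent[u]
      ring_edge[pedge[v]] <- TRUE; v <- parent[v]
    }
  }
  rb <- which(ring_edge)
  inring[c(m$from[rb], m$to[rb])] <- TRUE
  inring
}

# Number of aromatic rings = cycle rank of the aromatic subgraph
# (bonds - atoms + components), which equals the SSSR count per fused system.
n_aromatic_rings <- function(m) {
  ab <- which(m$arom)
  if (!length(ab)) return(0L)
  at <- sort(unique(c(m$from[ab], m$to[ab])))
  map <- match(seq_len(n_atoms(m)), at)
  sub <- new_molecule(m$elem[at], m$charge[at], m$nH[at],
                      map[m$from[ab]], map[m$to[ab]], m$order[ab],
                      m$arom[ab], m$arom_atom[at])
  length(ab) - length(at) + max(components(sub))
}

# Smallest set of smallest rings.  Shortest cycle through every ring bond,
# then a greedy linearly independent (GF(2) edge space) subset of cycle-rank
# size.  Molecules here are small, so the plain BFS formulation is fine.
sssr <- function(m) {
  n <- n_atoms(m); b <- n_bonds(m)
  if (b == 0L) return(list())
  rank <- b - n + max(components(m))
  if (rank <= 0L) return(list())
  adj <- adjacency_list(m)
  bond_id <- function(f, t) which((m$from == pmin(f, t)) &
                                  (m$to == pmax(f, t)))
  cycles <- list()
  for (k in seq_len(b)) {
    src <- m$from[k]; dst <- m$to[k]
    # BFS from src to dst avoiding bond k
    prev <- integer(n); prev[src] <- -1L
    queue <- src; found <- FALSE
    while (length(queue) && !found) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (v == src && w == dst) next
        if (v == dst && w == src) next
        if (prev[w] == 0L) {
          prev[w] <- v
          if (w == dst) { found <- TRUE; break }
          queue <- c(queue, w)
        }
      }
    }
    if (!found) next
    path <- dst; v <- dst
    while (prev[v] != -1L) { v <- prev[v]; path <- c(path, v) }
    cycles[[length(cycles) + 1L]] <- rev(path)
  }
  if (!length(cycles)) return(list())
  sizes <- lengths(cycles)
  ordc <- order(sizes)
  basis <- matrix(FALSE, 0L, b)
  chosen <- list()
  for (ci in ordc) {
    ring <- cycles[[ci]]
    ev <- logical(b)
    for (j in seq_along(ring)) {
      f <- ring[j]; t <- ring[if (j == length(ring)) 1L else j + 1L]
      ev[bond_id(f, t)] <- TRUE
    }
    v <- ev
    if (nrow(basis)) for (r in seq_len(nrow(basis))) {
      piv <- which(basis[r, ])[1L]
      if (v[piv]) v <- xor(v, basis[r, ])
    }
    if (any(v)) {
      basis <- rbind(basis, v)
      chosen[[length(chosen) + 1L]] <- ring
      if (length(chosen) == rank) break
    }
  }
  chosen
}

# Counts used by the synthetic-accessibility penalties.
ring_features <- function(m) {
  rings <- sssr(m)
  nmacro <- sum(lengths(rings) > 8L)
  nspiro <- 0L; bridge <- integer(0)
  if (length(rings) >= 2L) {
    spiro_atoms <- integer(0)
    for (i in seq_len(length(rings) - 1L)) for (j in (i + 1L):length(rings)) {
      shared <- intersect(rings[[i]], rings[[j]])
      if (length(shared) == 1L) spiro_atoms <- c(spiro_atoms, shared)
      if (length(shared) >= 3L) {
        # fused across >=2 bonds: the shared-path endpoints are bridgeheads
        deg_in <- vapply(shared, function(a) {
          nb <- intersect(c(m$to[m$from == a], m$from[m$to == a]), shared)
          length(nb)
        }, 0L)
        bridge <- c(bridge, shared[deg_in == 1L])
      }
    }
    nspiro <- length(unique(spiro_atoms))
  }
  list(n_rings = length(rings), n_macrocycles = nmacro,
       n_spiro = nspiro, n_bridgeheads = length(unique(bridge)),
       rings = rings)
}
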