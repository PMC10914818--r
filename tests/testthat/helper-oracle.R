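# Independent brute-force action enumerator.
#
# Re-derives the legal edit set from first principles: apply every
# conceivable single edit, recompute valence sums from scratch, keep the
# candidates that satisfy the valence table, deduplicate by canonical
# SMILES.  Shares only the molecule container and the OpenBabel
# serializer with the implementation under test; all enumeration logic is
# separate.

.BF_VALENCE <- c(C = 4L, N = 3L, O = 2L)

bf_bond_sums <- function(m) {
  n <- length(m$elem)
  s <- integer(n)
  for (k in seq_along(m$from)) {
    s[m$from[k]] <- s[m$from[k]] + m$order[k]
    s[m$to[k]] <- s[m$to[k]] + m$order[k]
  }
  s
}

# Recompute implicit hydrogens from the valence table; NULL if impossible.
bf_revalidate <- function(m) {
  bs <- bf_bond_sums(m)
  nH <- .BF_VALENCE[m$elem] - bs
  if (any(is.na(nH)) || any(nH < 0L)) return(NULL)
  m$nH <- as.integer(unname(nH))
  m
}

bf_connected_part <- function(m, keep_lowest_tie = TRUE) {
  n <- length(m$elem)
  comp <- integer(n); cur <- 0L
  adj <- vector("list", n)
  for (k in seq_along(m$from)) {
    adj[[m$from[k]]] <- c(adj[[m$from[k]]], m$to[k])
    adj[[m$to[k]]] <- c(adj[[m$to[k]]], m$from[k])
  }
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    q <- s; comp[s] <- cur
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (!comp[w]) { comp[w] <- cur; q <- c(q, w) }
    }
  }
  if (max(comp) == 1L) return(m)
  sizes <- tabulate(comp)
  big <- which(sizes == max(sizes))
  if (length(big) > 1L)
    big <- big[which.min(vapply(big, function(cc) min(which(comp == cc)),
                                0L))]
  at <- which(comp == big)
  map <- match(seq_len(n), at)
  bk <- comp[m$from] == big
  list(elem = m$elem[at], charge = m$charge[at], nH = m$nH[at],
       from = map[m$from[bk]], to = map[m$to[bk]], order = m$order[bk],
       arom = m$arom[bk], arom_atom = m$arom_atom[at])
}

bf_as_molecule <- function(g) {
  mm <- structure(g[c("elem", "charge", "nH", "from", "to", "order",
                      "arom", "arom_atom")], class = "molecule")
  mm
}

# All candidate molecules reachable in one edit, as canonical SMILES.
brute_force_actions <- function(m, elements = c("C", "N", "O"),
                                orders = 1:3) {
  g <- unclass(m)
  n <- length(g$elem)
  raw <- list()
  add <- function(gg) {
    gg2 <- bf_revalidate(gg)
    if (!is.null(gg2)) raw[[length(raw) + 1L]] <<- bf_as_molecule(gg2)
  }
  triple_ok <- function(e1, e2) all(c(e1, e2) %in% c("C", "N"))
  # atom additions
  for (i in seq_len(n)) for (e in elements) for (b in orders) {
    if (b == 3L && !triple_ok(g$elem[i], e)) next
    gg <- g
    gg$elem <- c(gg$elem, e); gg$charge <- c(gg$charge, 0L)
    gg$nH <- c(gg$nH, 0L); gg$arom_atom <- c(gg$arom_atom, FALSE)
    gg$from <- c(gg$from, i); gg$to <- c(gg$to, n + 1L)
    gg$order <- c(gg$order, b); gg$arom <- c(gg$arom, FALSE)
    add(gg)
  }
  # new bonds between unbonded pairs
  if (n >= 2L) {
    bonded <- paste(g$from, g$to)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (paste(i, j) %in% bonded) next
      for (b in orders) {
        if (b == 3L && !triple_ok(g$elem[i], g$elem[j])) next
        gg <- g
        gg$from <- c(gg$from, i); gg$to <- c(gg$to, j)
        gg$order <- c(gg$order, b); gg$arom <- c(gg$arom, FALSE)
        add(gg)
      }
    }
  }
  # order changes on existing non-aromatic bonds (increments, decrements,
  # deletions)
  for (k in seq_along(g$from)) {
    if (g$arom[k]) next
    o <- g$order[k]
    if (o < 3L && (o + 1L) %in% orders &&
        (o + 1L < 3L || triple_ok(g$elem[g$from[k]], g$elem[g$to[k]]))) {
      gg <- g; gg$order[k] <- o + 1L
      add(gg)
    }
    if (o >= 2L) {
      gg <- g; gg$order[k] <- o - 1L
      add(gg)
    }
    gg <- g
    keep <- setdiff(seq_along(g$from), k)
    gg$from <- g$from[keep]; gg$to <- g$to[keep]
    gg$order <- g$order[keep]; gg$arom <- g$arom[keep]
    gg2 <- bf_revalidate(gg)
    if (!is.null(gg2)) {
      part <- bf_connected_part(gg2)
      raw[[length(raw) + 1L]] <- bf_as_molecule(part)
    }
  }
  raw[[length(raw) + 1L]] <- m   # no modification
  smis <- canonical_smiles(lapply(raw, function(x) {
    attr(x, "cansmi") <- NULL; attr(x, "key") <- NULL
    attr(x, "codes") <- NULL; x
  }))
  sort(unique(smis))
}

# Canonical SMILES of the implementation's candidate set.
impl_action_smiles <- function(m, cfg) {
  s <- initial_state(m, cfg)
  cands <- enumerate_actions(s, cfg)
  sort(unique(canonical_smiles(lapply(cands, function(x) {
    attr(x, "cansmi") <- NULL; attr(x, "key") <- NULL
    attr(x, "codes") <- NULL; x
  }))))
}
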