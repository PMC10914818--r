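# Molecule-modification Markov decision process.
#
# A state is the current molecule plus a step counter bounded by the
# configured step limit (default 16 edits away from the lead).  The action
# space is the MolDQN family: atom addition, bond addition (ring closure or
# order increment), bond removal (decrement or deletion), and the identity
# "no modification".  Aromatic bonds are frozen: they are never removed or
# incremented, which preserves the perceived aromatic systems of the lead.

#' MDP configuration
#'
#' @param step_limit maximum number of edits per episode (study setting 16).
#' @param elements allowed elements for atom additions.
#' @param bond_orders allowed new-bond orders.
#' @param allow_increment include order increments on existing bonds among
#'   the bond-addition actions.
#' @param allow_ring_closure include new bonds between already-present
#'   atoms (ring formation).
#' @param dedup candidate identity: `"key"` (structural-invariant key, fast,
#'   used in the RL loop) or `"canonical"` (canonical-SMILES equality).
#'   The two are equivalent wherever the invariant is collision-free; the
#'   test suite verifies this on an exhaustive small-molecule universe.
#' @return an object of class `mdp_config`.
#' @export
mdp_config <- function(step_limit = 16L, elements = c("C", "N", "O"),
                       bond_orders = 1:3, allow_increment = TRUE,
                       allow_ring_closure = TRUE,
                       dedup = c("key", "canonical")) {
  if (!is.numeric(step_limit) || step_limit < 1L)
    stop("step_limit must be >= 1", call. = FALSE)
  if (!length(elements))
    stop("element set must be non-empty", call. = FALSE)
  if (!all(elements %in% names(PERMITTED_VALENCE)))
    stop("unknown element(s): ",
         paste(setdiff(elements, names(PERMITTED_VALENCE)), collapse = ", "),
         call. = FALSE)
  if (!all(bond_orders %in% 1:3))
    stop("bond orders must lie in {1,2,3}", call. = FALSE)
  structure(list(step_limit = as.integer(step_limit),
                 elements = as.character(elements),
                 bond_orders = sort(as.integer(bond_orders)),
                 allow_increment = isTRUE(allow_increment),
                 allow_ring_closure = isTRUE(allow_ring_closure),
                 dedup = match.arg(dedup)),
            class = "mdp_config")
}

#' Initial MDP state wrapping the unmodified lead
#'
#' @param lead a valid `molecule`.
#' @param cfg an `mdp_config`.
#' @return an object of class `mdp_state`.
#' @export
initial_state <- function(lead, cfg) {
  if (!inherits(lead, "molecule"))
    stop("lead must be a molecule", call. = FALSE)
  v <- validate_molecule(lead)
  if (!isTRUE(v)) stop("invalid lead: ", v, call. = FALSE)
  if (!is_connected(lead))
    stop("lead must be a single connected graph", call. = FALSE)
  structure(list(mol = lead, steps_taken = 0L,
                 step_limit = cfg$step_limit),
            class = "mdp_state")
}

#' @export
print.mdp_state <- function(x, ...) {
  cat(sprintf("<mdp_state: step %d/%d%s>\n", x$steps_taken, x$step_limit,
              if (is_terminal(x)) ", terminal" else ""))
  print(x$mol)
  invisible(x)
}

#' Is a state terminal?
#' @param s an `mdp_state`.
#' @export
is_terminal <- function(s) s$steps_taken >= s$step_limit

# --- graph edits ------------------------------------------------------------

.strip_cache <- function(m) { attr(m, "cansmi") <- NULL; m }

.edit_add_atom <- function(m, i, elem, b) {
  n <- n_atoms(m)
  nH <- m$nH; nH[i] <- nH[i] - b
  new_molecule(c(m$elem, elem), c(m$charge, 0L),
               c(nH, PERMITTED_VALENCE[[elem]] - b),
               c(m$from, i), c(m$to, n + 1L), c(m$order, b),
               c(m$arom, FALSE), c(m$arom_atom, FALSE))
}

.edit_add_bond <- function(m, i, j, b) {
  nH <- m$nH; nH[i] <- nH[i] - b; nH[j] <- nH[j] - b
  new_molecule(m$elem, m$charge, nH,
               c(m$from, min(i, j)), c(m$to, max(i, j)), c(m$order, b),
               c(m$arom, FALSE), m$arom_atom)
}

.edit_set_order <- function(m, k, delta) {
  nH <- m$nH
  nH[m$from[k]] <- nH[m$from[k]] - delta
  nH[m$to[k]] <- nH[m$to[k]] - delta
  order <- m$order; order[k] <- order[k] + delta
  new_molecule(m$elem, m$charge, nH, m$from, m$to, order, m$arom,
               m$arom_atom)
}

# Delete bond k entirely; if that disconnects the graph, keep the largest
# fragment (ties: the fragment holding the lowest original atom index).
.edit_delete_bond <- function(m, k) {
  nH <- m$nH
  nH[m$from[k]] <- nH[m$from[k]] + m$order[k]
  nH[m$to[k]] <- nH[m$to[k]] + m$order[k]
  keep <- setdiff(seq_len(n_bonds(m)), k)
  m2 <- new_molecule(m$elem, m$charge, nH, m$from[keep], m$to[keep],
                     m$order[keep], m$arom[keep], m$arom_atom)
  comp <- components(m2)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    big <- which(sizes == max(sizes))
    if (length(big) > 1L)
      big <- big[which.min(vapply(big, function(cc) min(which(comp == cc)),
                                  0L))]
    at <- which(comp == big)
    map <- match(seq_len(n_atoms(m2)), at)
    bkeep <- comp[m2$from] == big
    m2 <- new_molecule(m2$elem[at], m2$charge[at], m2$nH[at],
                       map[m2$from[bkeep]], map[m2$to[bkeep]],
                       m2$order[bkeep], m2$arom[bkeep], m2$arom_atom[at])
  }
  m2
}

.triple_ok <- function(e1, e2) e1 %in% c("C", "N") && e2 %in% c("C", "N")

#' Enumerate the legal actions of a state
#'
#' Returns the deduplicated set of candidate molecules reachable in one
#' edit: atom additions at every free valence, bond additions (ring
#' closures between unbonded atom pairs and order increments on existing
#' non-aromatic bonds), bond removals (order decrements and deletions,
#' keeping the largest fragment when a deletion disconnects the graph), and
#' the unchanged molecule.  Every candidate is valence-valid by
#' construction; triple bonds are restricted to C/N pairs.
#'
#' @param s a non-terminal `mdp_state`.
#' @param cfg an `mdp_config`.
#' @return list of `molecule` candidates (the current molecule included).
#' @export
enumerate_actions <- function(s, cfg) {
  if (is_terminal(s))
    stop("cannot enumerate actions of a terminal state", call. = FALSE)
  m <- s$mol
  n <- n_atoms(m)
  out <- list()
  ## (a) atom additions
  for (i in seq_len(n)) {
    fv <- m$nH[i]
    if (fv < 1L) next
    for (elem in cfg$elements) {
      maxb <- min(fv, PERMITTED_VALENCE[[elem]], 3L)
      for (b in cfg$bond_orders) {
        if (b > maxb) next
        if (b == 3L && !.triple_ok(m$elem[i], elem)) next
        out[[length(out) + 1L]] <- .edit_add_atom(m, i, elem, b)
      }
    }
  }
  ## (b) bond additions: ring closures ...
  if (cfg$allow_ring_closure && n >= 2L) {
    bonded <- paste(m$from, m$to)
    for (i in seq_len(n - 1L)) {
      if (m$nH[i] < 1L) next
      for (j in (i + 1L):n) {
        if (m$nH[j] < 1L) next
        if (paste(i, j) %in% bonded) next
        maxb <- min(m$nH[i], m$nH[j], 3L)
        for (b in cfg$bond_orders) {
          if (b > maxb) next
          if (b == 3L && !.triple_ok(m$elem[i], m$elem[j])) next
          out[[length(out) + 1L]] <- .edit_add_bond(m, i, j, b)
        }
      }
    }
  }
  ## ... and order increments on existing non-aromatic bonds
  if (cfg$allow_increment && n_bonds(m) > 0L) {
    for (k in seq_len(n_bonds(m))) {
      if (m$arom[k] || m$order[k] >= 3L) next
      if (m$nH[m$from[k]] < 1L || m$nH[m$to[k]] < 1L) next
      neworder <- m$order[k] + 1L
      if (!(neworder %in% cfg$bond_orders)) next
      if (neworder == 3L &&
          !.triple_ok(m$elem[m$from[k]], m$elem[m$to[k]])) next
      out[[length(out) + 1L]] <- .edit_set_order(m, k, 1L)
    }
  }
  ## (c) bond removals: decrement, and full deletion
  if (n_bonds(m) > 0L) {
    for (k in seq_len(n_bonds(m))) {
      if (m$arom[k]) next
      if (m$order[k] >= 2L)
        out[[length(out) + 1L]] <- .edit_set_order(m, k, -1L)
      del <- .edit_delete_bond(m, k)
      if (n_atoms(del) >= 1L)
        out[[length(out) + 1L]] <- del
    }
  }
  ## (d) no modification
  out[[length(out) + 1L]] <- m
  ## deduplicate; cache codes and keys on the survivors so downstream
  ## featurization and identity checks reuse them
  if (cfg$dedup == "canonical") {
    cs <- canonical_smiles(lapply(out, .strip_cache))
    keep <- !duplicated(cs)
    out <- out[keep]
    for (ii in seq_along(out)) attr(out[[ii]], "cansmi") <- cs[keep][ii]
  } else {
    keys <- character(length(out))
    for (ii in seq_along(out)) {
      cc <- circular_codes(out[[ii]], 3L)
      attr(out[[ii]], "codes") <- cc
      k <- mol_key(out[[ii]])
      attr(out[[ii]], "key") <- k
      keys[ii] <- k
    }
    out <- out[!duplicated(keys)]
  }
  out
}

#' Apply a chosen action
#'
#' @param s a non-terminal `mdp_state`.
#' @param chosen a molecule from `enumerate_actions(s, cfg)`.
#' @param cfg the `mdp_config` used for enumeration.
#' @param candidates optional pre-computed candidate list (skips
#'   re-enumeration; the caller vouches that it came from
#'   `enumerate_actions(s, cfg)`).
#' @return the successor `mdp_state`.
#' @export
mdp_step <- function(s, chosen, cfg, candidates = NULL) {
  if (is_terminal(s)) stop("state is terminal", call. = FALSE)
  if (is.null(candidates)) candidates <- enumerate_actions(s, cfg)
  key <- mol_key(chosen)
  keys <- vapply(candidates, mol_key, "")
  if (!key %in% keys)
    stop("chosen molecule is not a legal action of this state",
         call. = FALSE)
  structure(list(mol = chosen, steps_taken = s$steps_taken + 1L,
                 step_limit = s$step_limit),
            class = "mdp_state")
}
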