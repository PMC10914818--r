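# Random valence-valid molecule generator for property-style tests.
# Builds a random connected multigraph over C/N/O atom by atom, accepting
# only edits that keep every atom within its permitted valence, then
# round-trips through canonical SMILES.  Uses the session RNG so callers
# control the seed.

random_valid_smiles <- function(n_atoms_max = 8L) {
  val <- c(C = 4L, N = 3L, O = 2L)
  elems <- sample(names(val), 1L)
  from <- integer(0); to <- integer(0); order <- integer(0)
  n_target <- sample(2:n_atoms_max, 1L)
  while (length(elems) < n_target) {
    e <- sample(names(val), 1L)
    bs <- integer(length(elems))
    for (k in seq_along(from)) {
      bs[from[k]] <- bs[from[k]] + order[k]
      bs[to[k]] <- bs[to[k]] + order[k]
    }
    free <- val[elems] - bs
    cand <- which(free >= 1L)
    if (!length(cand)) break
    i <- if (length(cand) == 1L) cand else sample(cand, 1L)
    bmax <- min(free[i], val[e], 3L)
    if (bmax == 3L && !(elems[i] %in% c("C", "N") && e %in% c("C", "N")))
      bmax <- 2L
    b <- sample(seq_len(bmax), 1L)
    from <- c(from, i); to <- c(to, length(elems) + 1L)
    order <- c(order, b)
    elems <- c(elems, e)
  }
  # occasionally close a ring
  if (length(elems) >= 3L && stats::runif(1) < 0.4) {
    bs <- integer(length(elems))
    for (k in seq_along(from)) {
      bs[from[k]] <- bs[from[k]] + order[k]
      bs[to[k]] <- bs[to[k]] + order[k]
    }
    free <- val[elems] - bs
    open <- which(free >= 1L)
    if (length(open) >= 2L) {
      ij <- sample(open, 2L)
      ij <- sort(ij)
      if (!any(from == ij[1] & to == ij[2])) {
        from <- c(from, ij[1]); to <- c(to, ij[2])
        order <- c(order, 1L)
      }
    }
  }
  m <- structure(list(elem = elems, charge = integer(length(elems)),
                      nH = integer(length(elems)), from = from, to = to,
                      order = order, arom = logical(length(from)),
                      arom_atom = logical(length(elems))),
                 class = "molecule")
  g <- bf_revalidate(unclass(m))
  if (is.null(g)) return(random_valid_smiles(n_atoms_max))
  canonical_smiles(list(bf_as_molecule(g)))[[1L]]
}

# Memoized smoke-scale runs shared by the acceptance blocks.
.acc_cache <- new.env(parent = emptyenv())

acceptance_run <- function(which = c("first", "second", "random")) {
  which <- match.arg(which)
  if (is.null(.acc_cache[[which]])) {
    cfg <- seeded_smoke_config()
    .acc_cache[[which]] <- run_optimization(
      cfg$lead, cfg$mdp, cfg$agent, cfg$reward,
      agent = if (which == "random") "random" else "dqn")
  }
  .acc_cache[[which]]
}
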