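# Circular (Morgan-type) atom environment codes.
#
# One vectorized pass produces, per atom, a pair of independent hash codes
# at every radius 0..r.  The codes drive three consumers:
#   * featurize()      - folded count fingerprint for the Q-network,
#   * mol_key()        - an order-independent structural identity key used
#                        to deduplicate candidate molecules cheaply
#                        (different key => different molecule),
#   * env_keys()       - per-(atom, radius) environment identifiers keyed
#                        into the synthetic-accessibility fragment table.
#
# All arithmetic is double-precision integer math below 2^53, modulo two
# 25-bit primes, so codes are bit-stable across platforms and sessions.

.H1M <- 33554393; .H2M <- 33554467       # moduli (primes < 2^25)
.H1P <- 92821;    .H2P <- 48271          # self-multipliers
.H1Q <- 31337;    .H2Q <- 65537          # fold multipliers

#' Circular atom-environment hash codes
#'
#' @param m a `molecule`.
#' @param radius maximum environment radius.
#' @return list with `h1`, `h2`: n x (radius+1) matrices of codes.
#' @keywords internal
circular_codes <- function(m, radius = 2L) {
  cached <- attr(m, "codes")
  if (!is.null(cached) && ncol(cached$h1) >= radius + 1L)
    return(list(h1 = cached$h1[, seq_len(radius + 1L), drop = FALSE],
                h2 = cached$h2[, seq_len(radius + 1L), drop = FALSE]))
  n <- n_atoms(m)
  deg <- integer(n)
  if (n_bonds(m) > 0L) deg <- tabulate(c(m$from, m$to), n)
  eidx <- match(m$elem, names(PERMITTED_VALENCE), nomatch = 0L)
  inring <- ring_membership(m)
  base <- ((((eidx * 8L + pmin(m$nH, 7L)) * 8L + pmin(deg, 7L)) * 8L +
              (m$charge + 3L)) * 2L + as.integer(m$arom_atom)) * 2L +
    as.integer(inring)
  h1 <- matrix(0, n, radius + 1L); h2 <- matrix(0, n, radius + 1L)
  h1[, 1L] <- (base * 48947) %% .H1M
  h2[, 1L] <- (base * 57559) %% .H2M
  if (n_bonds(m) > 0L && radius > 0L) {
    a <- c(m$from, m$to); nb <- c(m$to, m$from)
    bc <- rep.int(ifelse(m$arom, 4L, m$order), 2L)
    for (r in seq_len(radius)) {
      c1 <- h1[, r]; c2 <- h2[, r]
      contrib1 <- (c1[nb] * 37 + bc) %% .H1M
      contrib2 <- (c2[nb] * 41 + bc) %% .H2M
      o <- order(a, contrib1, contrib2)
      aa <- a[o]; cc1 <- contrib1[o]; cc2 <- contrib2[o]
      new1 <- (c1 * .H1P) %% .H1M
      new2 <- (c2 * .H2P) %% .H2M
      rl <- rle(aa)
      starts <- cumsum(c(1L, rl$lengths[-length(rl$lengths)]))
      for (k in seq_len(max(rl$lengths))) {
        sel <- rl$lengths >= k
        at <- rl$values[sel]; idx <- starts[sel] + k - 1L
        new1[at] <- (new1[at] * .H1Q + cc1[idx]) %% .H1M
        new2[at] <- (new2[at] * .H2Q + cc2[idx]) %% .H2M
      }
      h1[, r + 1L] <- new1; h2[, r + 1L] <- new2
    }
  }
  list(h1 = h1, h2 = h2)
}

#' Per-atom environment identifiers
#'
#' Character identifiers of the circular environment of every atom at radii
#' 0..`radius`; the keys of the packaged fragment-score table.
#'
#' @param m a `molecule`.
#' @param radius maximum radius (default 2, as in the fragment analysis).
#' @return character matrix, n atoms x (radius+1).
#' @keywords internal
env_keys <- function(m, radius = 2L) {
  cc <- circular_codes(m, radius)
  matrix(paste(cc$h1, cc$h2, sep = ":"), nrow = n_atoms(m))
}

#' Structural identity key of a molecule
#'
#' Order-independent key built from converged circular codes plus bond
#' multiset; identical molecules always share a key, and distinct keys
#' guarantee distinct molecules.  Used to deduplicate action candidates
#' without a canonicalization round trip.
#'
#' @param m a `molecule`.
#' @return a single string.
#' @keywords internal
mol_key <- function(m) {
  k <- attr(m, "key")
  if (!is.null(k)) return(k)
  r <- 3L
  cc <- circular_codes(m, r)
  ac <- sort(cc$h1[, r + 1L] * .H2M + cc$h2[, r + 1L])
  if (n_bonds(m) > 0L) {
    f <- cc$h1[m$from, r + 1L]; t <- cc$h1[m$to, r + 1L]
    bc <- ifelse(m$arom, 4L, m$order)
    ec <- sort((pmin(f, t) * 53 + pmax(f, t)) * 5 + bc)
  } else ec <- numeric(0)
  paste(n_atoms(m), n_bonds(m),
        paste(ac, collapse = ","), paste(ec, collapse = ","), sep = "|")
}

#' Fingerprint feature vector of a molecule
#'
#' Circular-substructure count fingerprint of the configured radius
#' folded to `width` slots (each slot carries the number of atom
#' environments hashing to it, so substructure multiplicities are
#' preserved), with the normalized steps-remaining fraction appended as
#' the state clock (vector length `width + 1`).
#'
#' @param m a `molecule`.
#' @param cfg an `agent_config` (uses `fp_radius`, `fp_width`).
#' @param steps_frac steps remaining divided by the step limit.
#' @return numeric vector of length `cfg$fp_width + 1`.
#' @export
featurize <- function(m, cfg, steps_frac = 0) {
  c(fp_bits_to_dense(featurize_bits(m, cfg), cfg$fp_width), steps_frac)
}

# Sparse form: sorted on-bit indices (1-based), one entry per environment
# instance so repeats encode counts; cheap to store in the replay buffer.
featurize_bits <- function(m, cfg) {
  cc <- circular_codes(m, cfg$fp_radius)
  bits <- (as.vector(cc$h1) * 31 + as.vector(cc$h2)) %% cfg$fp_width
  sort(as.integer(bits) + 1L)
}

fp_bits_to_dense <- function(bits, width) {
  as.numeric(tabulate(bits, width))
}
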