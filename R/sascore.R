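# Synthetic-accessibility score.
#
# Fragment-contribution formulation: the commonness of every circular atom
# environment (radii 0-2) in a large compound collection gives a fragment
# score; molecular complexity penalties (size, stereo, spiro, bridgehead,
# macrocycle) and a symmetry correction are added and the result is mapped
# to the conventional 1 (easy) .. 10 (hard) scale.  The packaged table
# (inst/extdata/sa_fragment_scores.tsv) keys the published
# fragment-frequency scores by this package's own environment identifiers;
# environments missing from the table take the conventional novelty
# default of -4.
#
# The pipeline reports SA rescaled to [0,1] with 1 = easiest:
# (10 - raw) / 9.

.sa_env <- new.env(parent = emptyenv())

.sa_table <- function() {
  if (is.null(.sa_env$table)) {
    paths <- vapply(1:4, function(s)
      system.file("extdata", sprintf("sa_fragment_scores_%d.tsv", s),
                  package = "leadopt"), "")
    if (any(!nzchar(paths)))
      stop("fragment-score table not found; the package is incompletely ",
           "installed", call. = FALSE)
    tab <- do.call(rbind, lapply(paths, utils::read.table, header = TRUE,
                                 sep = "\t",
                                 colClasses = c("character", "numeric")))
    # shard keys are stored in base 36; decode to the decimal form that
    # env_keys() produces
    parts <- strsplit(tab$env, ":", fixed = TRUE)
    dec <- paste(strtoi(vapply(parts, `[`, "", 1L), 36L),
                 strtoi(vapply(parts, `[`, "", 2L), 36L), sep = ":")
    scores <- tab$score
    names(scores) <- dec
    .sa_env$table <- scores
  }
  .sa_env$table
}

#' Raw synthetic-accessibility score (1 = easy, 10 = hard)
#'
#' @param m a `molecule`.
#' @return numeric scalar in [1, 10].
#' @export
sa_score_raw <- function(m) {
  key <- paste0("sa:", mol_key(m))
  hit <- .reward_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- .sa_table()
  envs <- .emitted_environments(m, radius = 2L)
  sc <- tab[envs]
  sc[is.na(sc)] <- -4
  score1 <- mean(sc)

  n <- n_atoms(m)
  rf <- ring_features(m)
  size_penalty <- n^1.005 - n
  stereo_penalty <- 0            # generated edits are stereo-agnostic
  spiro_penalty <- log10(rf$n_spiro + 1)
  bridge_penalty <- log10(rf$n_bridgeheads + 1)
  macro_penalty <- if (rf$n_macrocycles > 0) log10(2) else 0
  score2 <- -size_penalty - stereo_penalty - spiro_penalty -
    bridge_penalty - macro_penalty

  nunique <- length(unique(envs))
  score3 <- if (n > nunique) log(n / nunique) * 0.5 else 0


  raw <- score1 + score2 + score3
  # map to the conventional 1..10 scale with a smoothed hard end
  lo <- -4.0; hi <- 2.5
  s <- 11 - (raw - lo + 1) / (hi - lo) * 9
  if (s > 8) s <- 8 + log(s + 1 - 9)
  s <- min(max(s, 1), 10)
  .reward_cache[[key]] <- s
  s
}

#' Normalized synthetic-accessibility score
#'
#' The raw 1-10 score linearly rescaled to [0,1] with 1 = easiest to
#' synthesize: `(10 - raw) / 9`.
#'
#' @param m a `molecule`.
#' @return numeric scalar in [0, 1].
#' @export
sa_score <- function(m) {
  sa_normalize(sa_score_raw(m))
}

#' Rescale a raw 1-10 synthetic-accessibility value to [0,1]
#' @param raw numeric vector of raw scores.
#' @export
sa_normalize <- function(raw) (10 - raw) / 9

# Environment instances contributing to the fragment score, following the
# circular-fingerprint emission convention: every atom contributes its
# radius-0 environment; a larger-radius environment is only emitted if its
# bond set (all bonds incident to atoms within radius-1 of the center) has
# not been produced before by any atom at any radius.
.emitted_environments <- function(m, radius = 2L) {
  n <- n_atoms(m)
  ek <- env_keys(m, radius)
  out <- ek[, 1L]
  if (n_bonds(m) == 0L || radius < 1L) return(out)
  adj <- adjacency_list(m)
  # all-pairs BFS distances (molecules here are small)
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (is.infinite(dist[s, w])) {
        dist[s, w] <- dist[s, v] + 1
        queue <- c(queue, w)
      }
    }
  }
  seen <- character(0)
  for (r in seq_len(radius)) {
    for (a in seq_len(n)) {
      inc <- dist[a, m$from] <= r - 1 | dist[a, m$to] <= r - 1
      if (!any(inc)) next
      bkey <- paste(which(inc), collapse = ",")
      if (bkey %in% seen) next
      seen <- c(seen, bkey)
      out <- c(out, ek[a, r + 1L])
    }
  }
  out
}
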