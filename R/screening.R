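# Post-run analytics over the episode log: the three-threshold candidate
# filter, fraction-better statistics, reward probability densities and
# episode-index trend tests.

#' Screening thresholds
#'
#' Defaults are the study's selection rule: SA >= 0.6, QED >= 0.7 and
#' affinity <= -10.0 kcal/mol, all inclusive (a candidate at exactly
#' QED 0.70 passes).
#'
#' @param sa_min minimum normalized SA score.
#' @param qed_min minimum QED score.
#' @param affinity_max maximum (most positive acceptable) affinity in
#'   kcal/mol.
#' @param inclusive logical: comparisons include the boundary.
#' @return an object of class `screening_thresholds`.
#' @export
screening_thresholds <- function(sa_min = 0.6, qed_min = 0.7,
                                 affinity_max = -10.0, inclusive = TRUE) {
  if (sa_min < 0 || sa_min > 1 || qed_min < 0 || qed_min > 1)
    stop("sa_min and qed_min must lie in [0,1]", call. = FALSE)
  structure(list(sa_min = sa_min, qed_min = qed_min,
                 affinity_max = affinity_max,
                 inclusive = isTRUE(inclusive)),
            class = "screening_thresholds")
}

#' Filter an episode log by the three thresholds
#'
#' Keeps records passing all three score thresholds, skipping malformed
#' records with a warning, in stable episode order, deduplicated by
#' canonical SMILES keeping the occurrence with the best scalar reward.
#'
#' @param log data.frame of episode records (as from
#'   [run_optimization()]).
#' @param t a `screening_thresholds`.
#' @return the passing subset of `log`.
#' @export
filter_candidates <- function(log, t = screening_thresholds()) {
  if (!nrow(log)) return(log)
  need <- c("smiles", "affinity_kcal_mol", "qed", "sa")
  miss <- setdiff(need, names(log))
  if (length(miss))
    stop("log lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !stats::complete.cases(log[need])
  if (any(bad)) {
    warning(sum(bad), " malformed record(s) skipped", call. = FALSE)
    log <- log[!bad, , drop = FALSE]
  }
  cmp_ge <- if (t$inclusive) `>=` else `>`
  cmp_le <- if (t$inclusive) `<=` else `<`
  pass <- cmp_ge(log$sa, t$sa_min) & cmp_ge(log$qed, t$qed_min) &
    cmp_le(log$affinity_kcal_mol, t$affinity_max)
  out <- log[pass, , drop = FALSE]
  if (!nrow(out)) return(out)
  # deduplicate by canonical SMILES, keeping the best scalar reward
  score <- if ("scalar_reward" %in% names(out)) out$scalar_reward
           else -out$affinity_kcal_mol
  best <- tapply(seq_len(nrow(out)), out$smiles,
                 function(ix) ix[which.max(score[ix])])
  out <- out[sort(unname(unlist(best))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proportion of scores beyond a threshold
#'
#' @param values numeric scores.
#' @param threshold cut point.
#' @param direction `"le"` (better = smaller, e.g. affinity) or `"ge"`
#'   (better = larger, e.g. QED/SA).
#' @param inclusive include the boundary.
#' @return proportion in [0,1].
#' @export
fraction_beyond <- function(values, threshold,
                            direction = c("le", "ge"),
                            inclusive = TRUE) {
  direction <- match.arg(direction)
  if (!length(values)) stop("empty input", call. = FALSE)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values", call. = FALSE)
  cmp <- switch(direction,
                le = if (inclusive) `<=` else `<`,
                ge = if (inclusive) `>=` else `>`)
  mean(cmp(values, threshold))
}

#' Kernel density of a reward distribution
#'
#' Gaussian kernel with Silverman's bandwidth on a 512-point grid,
#' renormalized to integrate to one exactly (trapezoid rule); degenerate
#' all-equal input is reported as a single point mass.
#'
#' @param values numeric scores (n >= 10).
#' @param bw bandwidth or rule (passed to [stats::density()]).
#' @return list with `x`, `y`, `modes` (local maxima, decreasing height)
#'   and `point_mass` (NULL, or the single value for degenerate input).
#' @export
reward_density <- function(values, bw = "nrd0") {
  values <- values[!is.na(values)]
  if (length(values) < 10L) stop("need at least 10 values", call. = FALSE)
  if (diff(range(values)) == 0)
    return(list(x = values[1L], y = Inf, modes = values[1L],
                point_mass = values[1L]))
  d <- stats::density(values, bw = bw, n = 512L)
  area <- sum(diff(d$x) * (utils::head(d$y, -1L) + utils::tail(d$y, -1L)) / 2)
  y <- d$y / area
  inner <- seq(2L, length(y) - 1L)
  is_max <- y[inner] > y[inner - 1L] & y[inner] >= y[inner + 1L]
  modes <- d$x[inner[is_max]][order(-y[inner[is_max]])]
  list(x = d$x, y = y, modes = modes, point_mass = NULL)
}

#' Trend of a reward against the episode index
#'
#' Spearman rank correlation of the chosen field with the episode index,
#' with a two-sided p-value; a constant field is flagged rather than
#' returning NaN.
#'
#' @param log episode-record data.frame.
#' @param field column to test (e.g. `"affinity_kcal_mol"`).
#' @return list with `rho`, `p_value`, `n`, `constant`.
#' @export
trend_statistic <- function(log, field = "affinity_kcal_mol") {
  if (!field %in% names(log)) stop("no column ", field, call. = FALSE)
  ok <- !is.na(log[[field]])
  x <- log$episode[ok]; y <- log[[field]][ok]
  if (length(y) < 10L) stop("need at least 10 records", call. = FALSE)
  if (diff(range(y)) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(y),
                constant = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(y),
       constant = FALSE)
}
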