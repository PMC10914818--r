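# Deterministic surrogate affinity oracle.
#
# A desk-scale stand-in for the docking engine with the additive form
#   affinity = sum(per-element contributions)
#            + (H-bond donor count) * donor bonus
#            + size-penalty * max(0, heavy atoms - pivot)      [kcal/mol]
# Parameters are fixed so the lead structure scores about -8 kcal/mol
# (the modal affinity of the optimized episodes) and so that polar
# enrichment of the lead is rewarded until molecules outgrow the pivot,
# giving the learner a smooth, bounded gradient.

#' Surrogate affinity parameters
#'
#' @param element_kcal named per-element contributions (kcal/mol).
#' @param donor_bonus_kcal bonus per H-bond donor group (negative).
#' @param size_penalty_kcal penalty per heavy atom beyond the pivot
#'   (non-negative).
#' @param size_pivot heavy-atom count where the size penalty starts.
#' @return an object of class `surrogate_params`.
#' @export
surrogate_params <- function(element_kcal = c(C = -0.20, N = -0.75,
                                              O = -0.65),
                             donor_bonus_kcal = -0.80,
                             size_penalty_kcal = 1.60,
                             size_pivot = 26L) {
  if (donor_bonus_kcal >= 0) stop("donor bonus must be negative",
                                  call. = FALSE)
  if (size_penalty_kcal < 0) stop("size penalty must be >= 0",
                                  call. = FALSE)
  structure(list(element_kcal = element_kcal,
                 donor_bonus_kcal = donor_bonus_kcal,
                 size_penalty_kcal = size_penalty_kcal,
                 size_pivot = as.integer(size_pivot)),
            class = "surrogate_params")
}

#' Deterministic surrogate binding affinity (kcal/mol)
#'
#' Identical on every call for the same molecule; more negative is
#' stronger.  H-bond donors are N/O atoms carrying at least one hydrogen.
#'
#' @param m a `molecule`.
#' @param params a `surrogate_params`.
#' @return affinity in kcal/mol.
#' @export
surrogate_affinity <- function(m, params = surrogate_params()) {
  contrib <- params$element_kcal[m$elem]
  contrib[is.na(contrib)] <- 0
  donors <- sum(m$elem %in% c("N", "O") & m$nH > 0L)
  sum(contrib) + donors * params$donor_bonus_kcal +
    params$size_penalty_kcal * max(0L, n_atoms(m) - params$size_pivot)
}

#' Reward configuration
#'
#' Binds the three reward evaluators and the scalarization used for
#' Q-learning: `w_aff * (-affinity/10) + w_qed * QED + w_sa * SA`.
#'
#' @param affinity `"surrogate"` for the deterministic oracle, or a
#'   function `molecule -> kcal/mol` (e.g. a docking adapter closure).
#' @param surrogate a `surrogate_params` (used when
#'   `affinity = "surrogate"`).
#' @param weights length-3 numeric: affinity, QED, SA weights.
#' @return an object of class `reward_config`.
#' @export
reward_config <- function(affinity = "surrogate",
                          surrogate = surrogate_params(),
                          weights = c(affinity = 1, qed = 1, sa = 1)) {
  if (!(identical(affinity, "surrogate") || is.function(affinity)))
    stop("affinity must be \"surrogate\" or a function", call. = FALSE)
  structure(list(affinity = affinity, surrogate = surrogate,
                 weights = weights),
            class = "reward_config")
}

#' Evaluate the three rewards of a molecule
#'
#' @param m a `molecule`.
#' @param cfg a `reward_config`.
#' @return list with `affinity` (kcal/mol), `qed`, `sa` (both in [0,1])
#'   and the scalarized `scalar`.
#' @export
reward_vector <- function(m, cfg = reward_config()) {
  aff <- if (is.function(cfg$affinity)) cfg$affinity(m)
         else surrogate_affinity(m, cfg$surrogate)
  if (!is.finite(aff)) stop("affinity oracle returned a non-finite value",
                            call. = FALSE)
  qed <- qed_score(m)
  sa <- sa_score(m)
  w <- cfg$weights
  list(affinity = aff, qed = qed, sa = sa,
       scalar = w[[1]] * (-aff / 10) + w[[2]] * qed + w[[3]] * sa)
}
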