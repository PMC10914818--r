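# Quantitative estimate of drug-likeness (QED).
#
# The standard formulation: eight physicochemical descriptors (molecular
# weight, calculated logP, H-bond acceptors and donors, topological polar
# surface area, rotatable bonds, aromatic rings, structural alerts) are
# each mapped through an asymmetric double-sigmoid desirability function
# and combined as a weighted geometric mean.  Descriptors are computed
# with OpenBabel (Wildman-Crippen logP, Ertl TPSA) plus the package's own
# ring perception; the desirability coefficients, acceptor SMARTS and the
# 116 structural-alert SMARTS are the published parameter set
# (R/qed_data.R).

.reward_cache <- new.env(parent = emptyenv())

# In-memory SDFset of a single molecule (ChemmineOB entry point).
# OBMol references for a molecule (handles bond-less single atoms, which
# the SDFset container rejects).
.as_obmol <- function(m) {
  txt <- paste0(write_molblock(m), "\n$$$$\n")
  refs <- list()
  ChemmineOB::forEachMol("SDF", txt, function(x)
    refs[[length(refs) + 1L]] <<- x)
  if (!length(refs))
    stop("OpenBabel could not read the molecule", call. = FALSE)
  refs
}

.smarts_count <- function(ob, pattern) {
  as.numeric(suppressWarnings(
    ChemmineOB::smartsSearch_OB(ob, pattern, uniqueMatches = TRUE)))[1L]
}

#' The eight QED descriptors of a molecule
#'
#' @param m a `molecule`.
#' @return named numeric vector: `MW`, `ALOGP`, `HBA`, `HBD`, `PSA`,
#'   `ROTB`, `AROM`, `ALERTS`.
#' @export
qed_properties <- function(m) {
  # one OBMol conversion reused by every descriptor and SMARTS query
  ob <- .as_obmol(m)
  pr <- tryCatch(suppressWarnings(ChemmineOB::prop_OB(ob)),
                 error = function(e)
                   stop("descriptor computation failed (prop_OB): ",
                        conditionMessage(e), call. = FALSE))
  for (need in c("MW", "logP", "TPSA", "HBD"))
    if (is.null(pr[[need]]) || is.na(pr[[need]]))
      stop("descriptor failure: ", need, call. = FALSE)
  hba <- sum(vapply(.QED_ACCEPTOR_SMARTS, function(p)
    .smarts_count(ob, p), 0))
  rotb <- .smarts_count(ob, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]")
  present <- unique(m$elem)
  alerts <- 0L
  for (i in seq_len(nrow(.QED_ALERTS))) {
    req <- .QED_ALERTS$req_elements[i]
    if (nzchar(req) &&
        !all(strsplit(req, ",", fixed = TRUE)[[1]] %in% present)) next
    cnt <- .smarts_count(ob, .QED_ALERTS$smarts[i])
    if (!is.na(cnt) && cnt >= .QED_ALERTS$min_count[i])
      alerts <- alerts + 1L
  }
  c(MW = pr$MW[1L], ALOGP = pr$logP[1L], HBA = hba, HBD = pr$HBD[1L],
    PSA = pr$TPSA[1L], ROTB = rotb, AROM = n_aromatic_rings(m),
    ALERTS = alerts)
}

# Asymmetric double sigmoid desirability, normalized by its maximum.
.ads <- function(x, p) {
  raw <- p["a"] + p["b"] /
    (1 + exp(-(x - p["c"] + p["d"] / 2) / p["e"])) *
    (1 - 1 / (1 + exp(-(x - p["c"] - p["d"] / 2) / p["f"])))
  unname(raw / p["dmax"])
}

#' Quantitative estimate of drug-likeness
#'
#' Weighted geometric mean of the eight desirability-transformed
#' descriptors; strictly inside (0, 1).
#'
#' @param m a `molecule`.
#' @return QED score in (0, 1).
#' @examples
#' \donttest{
#' qed_score(parse_smiles("c1ccccc1"))
#' }
#' @export
qed_score <- function(m) {
  key <- paste0("qed:", mol_key(m))
  hit <- .reward_cache[[key]]
  if (!is.null(hit)) return(hit)
  props <- qed_properties(m)
  d <- vapply(names(.QED_WEIGHTS), function(p)
    .ads(props[[p]], .QED_ADS[p, ]), 0)
  val <- exp(sum(.QED_WEIGHTS * log(d)) / sum(.QED_WEIGHTS))
  .reward_cache[[key]] <- val
  val
}
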