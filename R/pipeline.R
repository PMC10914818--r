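# Orchestration: the three pipeline stages as functions over a single run
# configuration, each writing its artifacts (plus a reproducibility
# manifest) under an output directory.  The numbered scripts in analysis/
# are thin drivers over these.

.write_manifest <- function(out_dir, config, extra = list()) {
  cfgfile <- file.path(out_dir, "config.json")
  jsonlite::write_json(.serializable(config), cfgfile, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- c(list(
    config_md5 = unname(tools::md5sum(cfgfile)),
    seed = config$agent$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("leadopt"))),
    extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.serializable <- function(x) {
  if (inherits(x, "molecule")) return(to_canonical_smiles(x))
  if (is.function(x)) return("<function>")
  if (is.list(x)) return(lapply(x, .serializable))
  x
}

#' Run the optimization stage and write its artifacts
#'
#' Writes `episodes.csv` (one record per episode), `trajectories.jsonl`
#' (one JSON line per edit), `manifest.json` / `config.json` (enough to
#' reproduce the run exactly in surrogate mode) and the Q-network weights.
#'
#' @param config a pipeline configuration (see [seeded_smoke_config()]).
#' @param out_dir output directory (created if needed).
#' @param agent `"dqn"` or `"random"`.
#' @param verbose print progress.
#' @return the episode-record data.frame, invisibly.
#' @export
run_optimize <- function(config = seeded_smoke_config(),
                         out_dir = "results/optimize",
                         agent = "dqn", verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- run_optimization(config$lead, config$mdp, config$agent,
                          config$reward, agent = agent,
                          trajectory_file = file.path(out_dir,
                                                      "trajectories.jsonl"),
                          verbose = verbose)
  utils::write.csv(log[, setdiff(names(log), "failed")],
                   file.path(out_dir, "episodes.csv"), row.names = FALSE)
  nets <- attr(log, "networks")
  if (!is.null(nets))
    saveRDS(nets$net, file.path(out_dir, "qnetwork.rds"))
  .write_manifest(out_dir, config,
                  list(stage = "optimize", agent = agent,
                       episodes = nrow(log)))
  invisible(log)
}

#' Run the screening stage over an episode log
#'
#' Computes the three-threshold candidate filter, the fraction of episodes
#' better than each threshold (inclusive and strict), reward densities and
#' episode trends; writes `passing.csv`, `screening.json` and per-reward
#' density tables.
#'
#' @param log episode data.frame or path to an `episodes.csv`.
#' @param thresholds a `screening_thresholds`.
#' @param out_dir output directory (or NULL to skip writing).
#' @return list with `passing`, `fractions`, `trends`, `densities`.
#' @export
run_screen <- function(log, thresholds = screening_thresholds(),
                       out_dir = "results/screen") {
  if (is.character(log)) {
    if (!file.exists(log)) stop("cannot read log: ", log, call. = FALSE)
    log <- utils::read.csv(log, stringsAsFactors = FALSE)
  }
  passing <- filter_candidates(log, thresholds)
  ok <- stats::complete.cases(log[c("affinity_kcal_mol", "qed", "sa")])
  fractions <- list()
  for (inc in c(TRUE, FALSE)) {
    key <- if (inc) "inclusive" else "strict"
    fractions[[key]] <- list(
      sa = fraction_beyond(log$sa[ok], thresholds$sa_min, "ge", inc),
      qed = fraction_beyond(log$qed[ok], thresholds$qed_min, "ge", inc),
      affinity = fraction_beyond(log$affinity_kcal_mol[ok],
                                 thresholds$affinity_max, "le", inc))
  }
  trends <- list(
    affinity = trend_statistic(log, "affinity_kcal_mol"),
    qed = trend_statistic(log, "qed"),
    sa = trend_statistic(log, "sa"))
  densities <- list(
    affinity = reward_density(log$affinity_kcal_mol[ok]),
    qed = reward_density(log$qed[ok]),
    sa = reward_density(log$sa[ok]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(passing, file.path(out_dir, "passing.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(thresholds = unclass(thresholds), fractions = fractions,
           trends = trends,
           modes = lapply(densities, function(d) d$modes[1])),
      file.path(out_dir, "screening.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    for (nm in names(densities))
      utils::write.csv(
        data.frame(x = densities[[nm]]$x, density = densities[[nm]]$y),
        file.path(out_dir, sprintf("density_%s.csv", nm)),
        row.names = FALSE)
  }
  list(passing = passing, fractions = fractions, trends = trends,
       densities = densities)
}

#' Run the docking-validation stage over screened candidates
#'
#' Docks each candidate into the grid box (20 poses by default), reports
#' the best energy per candidate and the hydrogen-bond contacts of the
#' best pose; writes `docking.csv` and `contacts.csv`.
#'
#' @param candidates character vector of SMILES (or list of molecules).
#' @param receptor path to the receptor PDB.
#' @param box a `grid_box`.
#' @param engine an `engine_config`.
#' @param poses poses requested per candidate.
#' @param out_dir output directory (or NULL to skip writing).
#' @return list with `energies` (data.frame) and `contacts` (data.frame).
#' @export
run_dock <- function(candidates, receptor,
                     box = seeded_smoke_config()$box,
                     engine = engine_config("mock"), poses = 20L,
                     out_dir = "results/dock") {
  prep <- prepare_receptor(receptor)
  mols <- if (is.character(candidates)) lapply(candidates, parse_smiles)
          else candidates
  energies <- vector("list", length(mols))
  contacts <- vector("list", length(mols))
  for (i in seq_along(mols)) {
    smi <- to_canonical_smiles(mols[[i]])
    ps <- dock(mols[[i]], prep$path, box, poses, engine)
    energies[[i]] <- data.frame(smiles = smi, best_kcal_mol = ps[[1]]$energy,
                                n_poses = length(ps),
                                stringsAsFactors = FALSE)
    hb <- detect_hbonds(ps[[1]], prep$pdb, box = box)
    if (nrow(hb)) hb <- cbind(smiles = smi, hb)
    contacts[[i]] <- hb
  }
  energies <- do.call(rbind, energies)
  keep <- vapply(contacts, nrow, 0L) > 0L
  contacts <- if (any(keep)) do.call(rbind, contacts[keep])
              else .empty_contacts()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(energies, file.path(out_dir, "docking.csv"),
                     row.names = FALSE)
    utils::write.csv(contacts, file.path(out_dir, "contacts.csv"),
                     row.names = FALSE)
    writeLines(grid_parameter_lines(box),
               file.path(out_dir, "grid_params.txt"))
  }
  list(energies = energies, contacts = contacts)
}
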