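# Build inst/extdata/sa_fragment_scores.tsv.
#
# The table maps this package's circular atom-environment identifiers
# (radii 0-2) to the published fragment-frequency scores used by the
# synthetic-accessibility method.  The corpus spans (a) the lead structure
# and random edit-walk molecules reachable from it, (b) small C/N/O
# molecules near the bottom of the action space, and (c) a set of common
# drug-like structures for breadth.  Scores for each environment are
# occurrence-weighted means of the per-atom scores assigned by the
# reference fragment catalog (see data-raw/sa_env_scores.py).
#
# Run from the repository root:
#   Rscript data-raw/make_sa_table.R

suppressMessages({library(ChemmineR); library(ChemmineOB)})
for (f in list.files("R", full.names = TRUE)) if (f != "R/zzz.R") source(f)

set.seed(20240305)

lead_smiles <- "c1ccc2c(c1)ncn2-c1ccc(nn1)-n1cnc2ccccc21"

random_walk <- function(start, steps, cfg) {
  s <- initial_state(start, cfg)
  out <- list()
  while (!is_terminal(s)) {
    cands <- enumerate_actions(s, cfg)
    sel <- sample.int(length(cands), 1L)
    s <- mdp_step(s, cands[[sel]], cfg, candidates = cands)
    out[[length(out) + 1L]] <- s$mol
  }
  out
}

cfg <- mdp_config(step_limit = 16L)
message("sampling edit walks from the lead ...")
mols <- list(parse_smiles(lead_smiles))
for (i in seq_len(120)) {
  mols <- c(mols, random_walk(mols[[1L]], 16L, cfg))
  if (i %% 20 == 0) message("  walk ", i)
}

message("sampling small-molecule walks ...")
cfg_small <- mdp_config(step_limit = 6L)
for (seed_smi in c("C", "CC", "CCO", "CN", "C=O", "c1ccccc1", "C1CCCCC1",
                   "c1ccncc1", "CC(=O)O", "CCN")) {
  for (i in seq_len(12))
    mols <- c(mols, random_walk(parse_smiles(seed_smi), 6L, cfg_small))
}

drugs <- c(
  "CC(=O)Oc1ccccc1C(=O)O",                    # aspirin
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",               # ibuprofen
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",               # caffeine
  "CC(=O)Nc1ccc(O)cc1",                       # paracetamol
  "c1ccc2c(c1)ccc(=O)o2",                     # coumarin
  "OCC1OC(O)C(O)C(O)C1O",                     # glucose
  "C1CCNCC1", "c1ccc2[nH]ccc2c1", "c1ccc2ncccc2c1",
  "Nc1ncnc2[nH]cnc12",                        # adenine
  "O=c1[nH]cnc2[nH]cnc12",                    # hypoxanthine
  "Cc1ccccc1", "COc1ccccc1", "Nc1ccccc1", "Oc1ccccc1",
  "O=C(O)c1ccccc1", "N#Cc1ccccc1", "O=Cc1ccccc1",
  "CC(N)C(=O)O", "NCCc1ccccc1", "NCCc1c[nH]c2ccccc12",
  "OC(=O)CCC(=O)O", "OC(=O)C=CC(=O)O", "CCOC(=O)C",
  "CC(C)=CCO", "C1CCOC1", "C1COCCN1", "C1CCNC1",
  "c1cnc2[nH]ccc2c1", "c1ccc(-c2ccccc2)cc1",
  "O=C(Nc1ccccc1)c1ccccc1", "CN(C)C=O", "CC#N", "CCOCC",
  "c1ccc(COc2ccccc2)cc1", "O=C1CCCCC1", "OC1CCCCC1",
  "C=CC(=O)OC", "CC(=O)NC", "NC(=O)c1ccccc1",
  "c1ccc(n2ccnc2)cc1",                        # phenylimidazole
  "c1ccc(-n2cnc3ccccc32)cc1"                  # phenylbenzimidazole
)
mols <- c(mols, lapply(drugs, parse_smiles))

message(length(mols), " corpus molecules; canonicalizing ...")
smi <- canonical_smiles(lapply(mols, function(m) { attr(m, "cansmi") <- NULL; m }))
keep <- !duplicated(smi)
mols <- mols[keep]; smi <- smi[keep]
message(length(mols), " unique")

writeLines(smi, "scratch/sa_corpus.smi")
system2("python",
        c("data-raw/sa_env_scores.py", "scratch/sa_corpus.smi",
          "scratch/sa_env_scores.tsv"))
ref <- read.table("scratch/sa_env_scores.tsv", header = TRUE, sep = "\t")

message("aligning environments ...")
# env keys must come from re-parsing the canonical SMILES handed to the
# reference scorer, so that atom indices agree on both sides (both parsers
# preserve SMILES appearance order)
parsed <- lapply(smi, parse_smiles)
rows <- vector("list", length(parsed))
for (i in seq_along(parsed)) {
  ek <- env_keys(parsed[[i]], radius = 2L)     # n x 3 (radius 0..2)
  rows[[i]] <- data.frame(mol = i - 1L,
                          atom = rep(seq_len(nrow(ek)) - 1L, 3L),
                          radius = rep(0:2, each = nrow(ek)),
                          env = as.vector(ek), stringsAsFactors = FALSE)
}
envdf <- do.call(rbind, rows)
mg <- merge(envdf, ref, by = c("mol", "atom", "radius"))
message(nrow(mg), " aligned of ", nrow(envdf), " environments")

agg <- aggregate(score ~ env, data = mg, FUN = stats::median)
cnt <- aggregate(score ~ env, data = mg, FUN = length)
names(cnt)[2] <- "n"
agg <- merge(agg, cnt, by = "env")

# priority: environments of the lead and of the reference molecules first,
# then by corpus frequency; the size budget is three shard files
priority_mols <- c(1L, seq(length(parsed) - length(drugs) + 1L,
                           length(parsed)))
prio_envs <- unique(unlist(lapply(parsed[priority_mols], function(m)
  as.vector(env_keys(m, radius = 2L)))))
agg$prio <- agg$env %in% prio_envs
agg <- agg[order(-agg$prio, -agg$n), ]
max_rows <- 7600L
agg <- agg[seq_len(min(nrow(agg), max_rows)), ]

# compact storage: keys re-encoded in base 36, scores to 4 significant
# digits (the fragment scores themselves carry ~4 digits)
b36 <- function(x) {
  digits <- c(0:9, letters)
  vapply(x, function(v) {
    v <- as.numeric(v); out <- ""
    repeat {
      out <- paste0(digits[v %% 36 + 1], out)
      v <- v %/% 36
      if (v == 0) break
    }
    out
  }, "")
}
parts <- strsplit(agg$env, ":", fixed = TRUE)
key36 <- paste(b36(vapply(parts, `[`, "", 1L)),
               b36(vapply(parts, `[`, "", 2L)), sep = ":")
out <- data.frame(env = key36, score = signif(agg$score, 4))
out <- out[order(out$env), ]
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
shard <- rep(seq_len(4L), length.out = nrow(out))
for (s in seq_len(4L)) {
  f <- sprintf("inst/extdata/sa_fragment_scores_%d.tsv", s)
  write.table(out[shard == s, ], f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  message("wrote ", f, ": ", sum(shard == s), " rows, ",
          file.size(f), " bytes")
}
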