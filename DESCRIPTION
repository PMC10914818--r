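Package: leadopt
Title: Lead-Structure Molecule Optimization by Deep Q-Learning with
    Docking-Based Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A step-limited molecule-modification Markov decision process
    optimized by a deep Q-network with linearly decaying epsilon-greedy
    exploration, rewarded by drug-likeness (QED), synthetic accessibility
    and predicted binding affinity.  Episodes start from a lead structure
    and apply valence-safe graph edits (atom addition, bond addition, bond
    removal, no-modification); optimized episode logs are screened by
    score thresholds and passing candidates are validated by docking-pose
    parsing and hydrogen-bond contact analysis.  SMILES handling,
    canonicalization and 3-D building delegate to OpenBabel; a
    deterministic surrogate affinity oracle, a toy receptor and mock
    docking-engine reports make the whole pipeline runnable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    bio3d,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
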