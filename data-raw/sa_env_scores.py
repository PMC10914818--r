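#!/usr/bin/env python
"""Per-atom-environment fragment scores for the SA table build.

Reads a SMILES file (one per line), computes for every atom environment at
radii 0..2 the published fragment-frequency score (the SA_Score
contribution data distributed with rdkit; unknown environments take the
conventional default -4), and writes a TSV: mol, atom, radius, score.
Atom indices follow SMILES appearance order, which both rdkit and
OpenBabel preserve, so the R side can align environments by index.

Usage: python data-raw/sa_env_scores.py corpus.smi env_scores.tsv
"""

import sys

from rdkit import Chem
from rdkit.Chem import rdFingerprintGenerator

sys.path.append("/opt/conda/envs/bio/share/RDKit/Contrib/SA_Score")
import sascorer  # noqa: E402

sascorer.readFragmentScores()
FSCORES = sascorer._fscores

gen = rdFingerprintGenerator.GetMorganGenerator(radius=2)


def main(smi_path, out_path):
    with open(smi_path) as fh:
        smiles = [ln.strip().split()[0] for ln in fh if ln.strip()]
    with open(out_path, "w") as out:
        out.write("mol\tatom\tradius\tscore\n")
        for mi, smi in enumerate(smiles):
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                sys.stderr.write("skip unparsable: %s\n" % smi)
                continue
            ao = rdFingerprintGenerator.AdditionalOutput()
            ao.AllocateBitInfoMap()
            gen.GetSparseCountFingerprint(mol, additionalOutput=ao)
            for bit, envs in ao.GetBitInfoMap().items():
                sc = FSCORES.get(bit, -4.0)
                for atom, radius in envs:
                    out.write("%d\t%d\t%d\t%r\n" % (mi, atom, radius, sc))
    print("done: %d molecules" % len(smiles))


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
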