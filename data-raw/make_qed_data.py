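#!/usr/bin/env python
"""Generate R/qed_data.R from the published QED parameterization.

The desirability-function coefficients, acceptor SMARTS and structural-alert
SMARTS are the published QED parameter set (Bickerton et al., Nature
Chemistry 4:90, 2012), as distributed with rdkit.  For each alert pattern we
also record a conservative set of required elements so that the R scorer can
skip patterns that cannot match a molecule's element content (the RL action
space is C/N/O only, where most alerts are structurally impossible).

Run from the repository root:  python data-raw/make_qed_data.py
"""

import re

from rdkit import Chem
from rdkit.Chem import QED

# Two published alert patterns are multi-component repeats ("x.x.x"), which
# express minimum counts of a single component; store them that way since
# component-level SMARTS is not universally supported.
SPECIAL = {
    "C(=O)O[C,H1].C(=O)O[C,H1].C(=O)O[C,H1]": ("C(=O)O[C,H1]", 3),
    "F.F.F.F": ("F", 4),
}

TWO_LETTER = ["Cl", "Br", "Si", "Se", "Na", "Li", "Mg", "Ca", "Fe", "Zn",
              "Cu", "Mn", "Al", "Sn", "Hg", "Pb", "As", "Sb", "Bi", "Te"]
ONE_LETTER = {"B": "B", "C": "C", "N": "N", "O": "O", "F": "F", "P": "P",
              "S": "S", "I": "I", "b": "B", "c": "C", "n": "N", "o": "O",
              "p": "P", "s": "S"}
ATOMIC = {5: "B", 6: "C", 7: "N", 8: "O", 9: "F", 15: "P", 16: "S",
          17: "Cl", 35: "Br", 53: "I", 14: "Si", 34: "Se"}


def required_elements(patt):
    """Elements an atom token definitely requires; conservative.

    A pattern atom contributes a requirement only when its SMARTS token is
    an unambiguous single-element primitive (no '!', ',', '*', '#X' with
    recursion, etc.).  Unparseable tokens contribute nothing, so the
    prefilter can only skip patterns that truly cannot match.
    """
    req = set()
    for atom in patt.GetAtoms():
        tok = atom.GetSmarts()
        if "!" in tok or "," in tok or "$" in tok or "*" in tok:
            continue
        body = tok[1:-1] if tok.startswith("[") else tok
        m = re.match(r"#(\d+)", body)
        if m:
            z = int(m.group(1))
            if z in ATOMIC:
                req.add(ATOMIC[z])
            continue
        for sym in TWO_LETTER:
            if body.startswith(sym):
                req.add(sym)
                break
        else:
            if body[:1] in ONE_LETTER:
                req.add(ONE_LETTER[body[:1]])
    return sorted(req)


def r_str(s):
    return '"' + s.replace("\\", "\\\\").replace('"', '\\"') + '"'


def main():
    lines = []
    lines.append("# Published QED parameterization (desirability coefficients,")
    lines.append("# acceptor SMARTS, structural-alert SMARTS).  Generated by")
    lines.append("# data-raw/make_qed_data.py; do not edit by hand.")
    lines.append("")
    props = ["MW", "ALOGP", "HBA", "HBD", "PSA", "ROTB", "AROM", "ALERTS"]
    lines.append(".QED_ADS <- matrix(c(")
    rows = []
    for p in props:
        v = QED.adsParameters[p]
        rows.append("  " + ", ".join(repr(x) for x in
                                     [v.A, v.B, v.C, v.D, v.E, v.F, v.DMAX]))
    lines.append(",\n".join(rows))
    lines.append('), nrow = 8, byrow = TRUE, dimnames = list(')
    lines.append('  c(%s),' % ", ".join(r_str(p) for p in props))
    lines.append('  c("a", "b", "c", "d", "e", "f", "dmax")))')
    lines.append("")
    w = QED.WEIGHT_MEAN
    lines.append(".QED_WEIGHTS <- c(%s)" % ", ".join(
        "%s = %r" % (p, getattr(w, p)) for p in props))
    lines.append("")
    acc = [Chem.MolToSmarts(a) for a in QED.Acceptors]
    lines.append(".QED_ACCEPTOR_SMARTS <- c(")
    lines.append(",\n".join("  " + r_str(a) for a in acc))
    lines.append(")")
    lines.append("")
    smarts, mincnt, reqs = [], [], []
    for a in QED.StructuralAlerts:
        s = Chem.MolToSmarts(a)
        if s in SPECIAL:
            comp, k = SPECIAL[s]
            patt = Chem.MolFromSmarts(comp)
            smarts.append(comp)
            mincnt.append(k)
            reqs.append(required_elements(patt))
        else:
            smarts.append(s)
            mincnt.append(1)
            reqs.append(required_elements(a))
    lines.append(".QED_ALERTS <- data.frame(")
    lines.append("  smarts = c(\n%s),"
                 % ",\n".join("    " + r_str(s) for s in smarts))
    lines.append("  min_count = c(%s)," % ", ".join(map(str, mincnt)))
    lines.append("  req_elements = c(\n%s),"
                 % ",\n".join("    " + r_str(",".join(r)) for r in reqs))
    lines.append("  stringsAsFactors = FALSE)")
    lines.append("")
    with open("R/qed_data.R", "w") as fh:
        fh.write("\n".join(lines) + "\n")
    print("wrote R/qed_data.R: %d alerts, %d acceptors"
          % (len(smarts), len(acc)))


if __name__ == "__main__":
    main()
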