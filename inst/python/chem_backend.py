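"""RDKit chemistry backend for the fragrl R package.

Runs either as a line-oriented JSON server on a localhost socket
(``python chem_backend.py server <port>``) or as a one-shot batch filter
(``python chem_backend.py batch`` reading a JSON array of requests on stdin).
Every request is ``{"op": <name>, "payload": {...}}``; every response is
``{"ok": true, "result": ...}`` or ``{"ok": false, "error": "..."}``.

All molecule lists are positional: result[i] corresponds to payload smiles[i],
with null for entries that fail to parse.
"""

import json
import os
import socket
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, QED, rdMolDescriptors
from rdkit.Chem.Scaffolds import MurckoScaffold
from rdkit.Chem import RDConfig

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

RDLogger.DisableLog("rdApp.*")


def _as_list(x):
    if isinstance(x, (str, int, float)):
        return [x]
    return list(x)


def _mol(smi):
    if smi is None:
        return None
    return Chem.MolFromSmiles(smi)


# ---------------------------------------------------------------- fragmentation

def _eligible_bonds(mol):
    """Acyclic single bonds with at least one ring-atom endpoint."""
    out = []
    for b in mol.GetBonds():
        if b.GetBondType() != Chem.BondType.SINGLE or b.IsInRing():
            continue
        if b.GetBeginAtom().IsInRing() or b.GetEndAtom().IsInRing():
            out.append(b.GetIdx())
    return out


def _canonical_fragment(frag):
    """Renumber attachment maps 1..m by canonical atom rank; return
    (canonical smiles, n_attach, {local_point: global_label})."""
    frag = Chem.Mol(frag)
    dummies = [a for a in frag.GetAtoms() if a.GetAtomicNum() == 0]
    globals_ = {a.GetIdx(): a.GetAtomMapNum() for a in dummies}
    for a in dummies:
        a.SetAtomMapNum(0)
    ranks = list(Chem.CanonicalRankAtoms(Chem.Mol(frag)))
    order = sorted(dummies, key=lambda a: ranks[a.GetIdx()])
    point_of_global = {}
    for k, a in enumerate(order, start=1):
        a.SetAtomMapNum(k)
        point_of_global[globals_[a.GetIdx()]] = k
    return Chem.MolToSmiles(frag), len(dummies), point_of_global


def _frag_class(frag, n_attach):
    if any(a.IsInRing() for a in frag.GetAtoms() if a.GetAtomicNum() > 0):
        return "ring"
    return "linker" if n_attach >= 2 else "side_chain"


def _heavy_count(mol):
    return sum(1 for a in mol.GetAtoms() if a.GetAtomicNum() > 0)


def op_fragment(payload):
    out = []
    for smi in _as_list(payload["smiles"]):
        mol = _mol(smi)
        if mol is None:
            out.append({"ok": False, "error": "parse error: %s" % smi})
            continue
        canonical = Chem.MolToSmiles(mol)
        bonds = _eligible_bonds(mol)
        if not bonds:
            n = mol.GetNumAtoms()
            out.append({
                "ok": True, "canonical": canonical,
                "fragments": [{
                    "smiles": canonical, "atom_count": n, "n_attach": 0,
                    "frag_class": _frag_class(mol, 0),
                }],
                "bonds": [],
            })
            continue
        labels = [(i + 1, i + 1) for i in range(len(bonds))]
        fmol = Chem.FragmentOnBonds(mol, bonds, dummyLabels=labels)
        # FragmentOnBonds stores the label in the dummy isotope field
        for a in fmol.GetAtoms():
            if a.GetAtomicNum() == 0 and a.GetIsotope() > 0:
                a.SetAtomMapNum(a.GetIsotope())
                a.SetIsotope(0)
        idx_groups = Chem.GetMolFrags(fmol)
        mol_groups = Chem.GetMolFrags(fmol, asMols=True, sanitizeFrags=True)
        parent_ranks = list(Chem.CanonicalRankAtoms(mol))
        n_parent = mol.GetNumAtoms()
        recs = []
        for atom_ids, sub in zip(idx_groups, mol_groups):
            smi_f, n_attach, point_of_global = _canonical_fragment(sub)
            order_key = min(parent_ranks[i] for i in atom_ids if i < n_parent)
            recs.append({
                "smiles": smi_f,
                "atom_count": _heavy_count(sub),
                "n_attach": n_attach,
                "frag_class": _frag_class(sub, n_attach),
                "order_key": order_key,
                "_points": point_of_global,
            })
        recs.sort(key=lambda r: r["order_key"])
        bond_graph = []
        for label in range(1, len(bonds) + 1):
            ends = [(pos, r["_points"][label])
                    for pos, r in enumerate(recs, start=1)
                    if label in r["_points"]]
            assert len(ends) == 2, "cleaved bond must bridge two fragments"
            (fa, pa), (fb, pb) = ends
            bond_graph.append([fa, pa, fb, pb])
        for r in recs:
            del r["_points"]
            del r["order_key"]
        out.append({"ok": True, "canonical": canonical,
                    "fragments": recs, "bonds": bond_graph})
    return out


def op_assemble(payload):
    out = []
    for job in payload["jobs"]:
        try:
            out.append(_assemble_one(job["frags"], job.get("bonds") or []))
        except Exception as exc:  # valence etc. -> invalid, not a crash
            out.append({"ok": False, "error": str(exc)})
    return out


def _assemble_one(frag_smis, bonds):
    mols = []
    for smi in frag_smis:
        m = _mol(smi)
        if m is None:
            return {"ok": False, "error": "fragment parse error: %s" % smi}
        mols.append(m)
    combined = mols[0]
    offsets = [0]
    for m in mols[1:]:
        offsets.append(combined.GetNumAtoms())
        combined = Chem.CombineMols(combined, m)
    rw = Chem.RWMol(combined)
    # locate each fragment's dummy atoms by local attachment number
    dummy_at = {}
    for fi, m in enumerate(mols):
        for a in m.GetAtoms():
            if a.GetAtomicNum() == 0 and a.GetAtomMapNum() > 0:
                dummy_at[(fi + 1, a.GetAtomMapNum())] = offsets[fi] + a.GetIdx()
    paired = set()
    for g, (fa, pa, fb, pb) in enumerate(bonds, start=1):
        ia, ib = dummy_at[(fa, pa)], dummy_at[(fb, pb)]
        rw.GetAtomWithIdx(ia).SetAtomMapNum(g)
        rw.GetAtomWithIdx(ib).SetAtomMapNum(g)
        paired.update((ia, ib))
    open_dummies = sorted((i for i in dummy_at.values() if i not in paired),
                          reverse=True)
    for i in open_dummies:  # open attachment points are capped with implicit H
        rw.RemoveAtom(i)
    mol = rw.GetMol()
    if bonds:
        mol = Chem.molzip(mol)
    Chem.SanitizeMol(mol)
    return {"ok": True, "smiles": Chem.MolToSmiles(mol)}


# ---------------------------------------------------------------- simple ops

def op_canonical(payload):
    out = []
    for smi in _as_list(payload["smiles"]):
        mol = _mol(smi)
        out.append(None if mol is None else Chem.MolToSmiles(mol))
    return out


def op_validity(payload):
    return [_mol(s) is not None for s in _as_list(payload["smiles"])]


def op_graph(payload):
    """Heavy-atom graph; attachment dummies are excluded from matching."""
    out = []
    for smi in _as_list(payload["smiles"]):
        mol = _mol(smi)
        if mol is None:
            out.append(None)
            continue
        keep = [a.GetIdx() for a in mol.GetAtoms() if a.GetAtomicNum() > 0]
        remap = {idx: k + 1 for k, idx in enumerate(keep)}
        atoms = [[mol.GetAtomWithIdx(i).GetAtomicNum(),
                  int(mol.GetAtomWithIdx(i).GetIsAromatic())] for i in keep]
        bonds = []
        for b in mol.GetBonds():
            i, j = b.GetBeginAtomIdx(), b.GetEndAtomIdx()
            if i in remap and j in remap:
                bonds.append(sorted([remap[i], remap[j]]))
        out.append({"atoms": atoms, "bonds": sorted(bonds)})
    return out


def op_descriptors(payload):
    out = []
    for smi in _as_list(payload["smiles"]):
        mol = _mol(smi)
        if mol is None:
            out.append({"valid": False})
            continue
        out.append({
            "valid": True,
            "mw": Descriptors.MolWt(mol),
            "logp": Crippen.MolLogP(mol),
            "tpsa": rdMolDescriptors.CalcTPSA(mol),
            "heavy": mol.GetNumHeavyAtoms(),
        })
    return out


def op_smarts(payload):
    pats = []
    for p in _as_list(payload["patterns"]):
        q = Chem.MolFromSmarts(p)
        if q is None:
            raise ValueError("invalid SMARTS pattern: %s" % p)
        pats.append(q)
    out = []
    for smi in _as_list(payload["smiles"]):
        mol = _mol(smi)
        if mol is None:
            out.append(None)
        else:
            out.append([int(mol.HasSubstructMatch(q)) for q in pats])
    return out


def op_scaffold(payload):
    out = []
    for smi in _as_list(payload["smiles"]):
        mol = _mol(smi)
        if mol is None:
            out.append(None)
        else:
            out.append(Chem.MolToSmiles(MurckoScaffold.GetScaffoldForMol(mol)))
    return out


def op_fingerprint(payload):
    nbits = int(payload.get("nbits", 2048))
    radius = int(payload.get("radius", 2))
    gen = rdMolDescriptors.GetMorganFingerprintAsBitVect
    out = []
    for smi in _as_list(payload["smiles"]):
        mol = _mol(smi)
        if mol is None:
            out.append(None)
        else:
            out.append(list(gen(mol, radius, nBits=nbits).GetOnBits()))
    return out


def op_sa(payload):
    out = []
    for smi in _as_list(payload["smiles"]):
        mol = _mol(smi)
        out.append(None if mol is None else sascorer.calculateScore(mol))
    return out


def op_qed(payload):
    out = []
    for smi in _as_list(payload["smiles"]):
        mol = _mol(smi)
        out.append(None if mol is None else QED.qed(mol))
    return out


def op_ping(payload):
    return "pong"


OPS = {
    "ping": op_ping,
    "canonical": op_canonical,
    "validity": op_validity,
    "fragment": op_fragment,
    "assemble": op_assemble,
    "graph": op_graph,
    "descriptors": op_descriptors,
    "smarts": op_smarts,
    "scaffold": op_scaffold,
    "fingerprint": op_fingerprint,
    "sa": op_sa,
    "qed": op_qed,
}


def handle(req):
    try:
        fn = OPS[req["op"]]
        return {"ok": True, "result": fn(req.get("payload") or {})}
    except Exception as exc:
        return {"ok": False, "error": "%s: %s" % (type(exc).__name__, exc)}


def serve(port):
    srv = socket.socket(socket.AF_INET, socket.SOCK_STREAM)
    srv.setsockopt(socket.SOL_SOCKET, socket.SO_REUSEADDR, 1)
    srv.bind(("127.0.0.1", port))
    srv.listen(1)
    sys.stdout.write("READY %d\n" % port)
    sys.stdout.flush()
    conn, _ = srv.accept()
    rfile = conn.makefile("r", encoding="utf-8")
    for line in rfile:
        line = line.strip()
        if not line:
            continue
        resp = handle(json.loads(line))
        conn.sendall((json.dumps(resp) + "\n").encode("utf-8"))
    conn.close()
    srv.close()


def batch():
    reqs = json.load(sys.stdin)
    if isinstance(reqs, dict):
        reqs = [reqs]
    json.dump([handle(r) for r in reqs], sys.stdout)
    sys.stdout.write("\n")


if __name__ == "__main__":
    mode = sys.argv[1] if len(sys.argv) > 1 else "batch"
    if mode == "server":
        serve(int(sys.argv[2]))
    else:
        batch()
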