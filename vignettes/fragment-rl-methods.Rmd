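---
title: "Methods: fragment-based molecular generation with A2C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-based molecular generation with A2C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the model it implements, the
parameters that matter, the numerical choices that were genuinely open, and
what the shipped tests do and do not establish. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The model

fragrl generates molecules by *fragment replacement* rather than
token-by-token synthesis. The pipeline has five layers.

**1. Fragmentation.** Every acyclic single bond with at least one ring-atom
endpoint is cleaved, splitting a molecule into ring systems, linkers
(acyclic, two or more attachment points) and side chains (acyclic, one
attachment point). Each cleavage leaves a numbered attachment-point pair,
so the decomposition map reassembles the input exactly — a property tested
on every fixture molecule. Bonds wholly inside rings are never cut, so ring
systems survive intact; the biphenyl-type bond between two ring atoms is
acyclic and therefore eligible. Multiple bonds (e.g. an exocyclic C=O) are
not cleaved: the rule is deliberately restricted to single bonds. Charged
or isotopic atoms are canonicalized but not normalized away.

**2. Fragment similarity and tree codes.** Fragment similarity is a
Tanimoto coefficient over maximum-common-substructure atom counts,

$$\mathrm{TMCS}(M_1, M_2) = \frac{mcs(M_1, M_2)}
  {a(M_1) + a(M_2) - mcs(M_1, M_2)},$$

where $a(\cdot)$ counts heavy atoms and $mcs$ is the heavy-atom size of the
maximum common *connected* substructure. The MCS comparator matches atoms
on element plus aromaticity and matches bonds regardless of order; the
attachment placeholders are excluded. These settings were an open choice —
no MCS parameterization is fixed by the method description — and heavy-atom
counting is the standard MCS convention. The search is an exact
branch-and-bound with an expansion budget; on fragment-sized graphs the
budget is never reached (the acceptance suite checks exact agreement with a
brute-force subgraph-enumeration oracle on 100 random pairs of up to 12
heavy atoms).

The library is then consolidated into a balanced binary tree, bottom-up:
each pairing round repeatedly merges the two most similar remaining trees
(inter-tree similarity = the *maximum* pairwise fragment similarity across
their members, i.e. single linkage), and rounds repeat until one tree
remains. We read the pairing as *strict round-based* pairing rather than
unconstrained greedy merging: round-based pairing halves the tree count
each round and is what keeps the tree balanced (depth exactly
$\log_2 n$ at powers of two, at most one extra level otherwise), which is
the stated point of the construction. A fragment's code is its
root-to-leaf path, "1" for a left branch, "0" for a right branch, so
similar fragments share prefixes. Determinism is pinned down by three
conventions the method description leaves open: similarities are compared
with an absolute tolerance of 1e-12 before tie-breaking; ties prefer the
pair with the lexicographically smallest (min library index, max library
index); within a merge, the operand containing the smaller minimum library
index becomes the left child. A single-leaf tree gets the empty code; the
policy pads codes to fixed length with a dedicated pad symbol.

**3. Policy.** A molecule state is its ordered fragment decomposition
(deterministic order: canonical-atom-rank of each fragment's first parent
atom) with a scaffold mask — ring and linker fragments are scaffold, side
chains are not, consistent with Bemis–Murcko usage. Fragment tokens (code
embedding + learned position embedding) feed a transformer encoder:
multi-head scaled-dot-product attention (logits divided by
$\sqrt{d_p}$ — the description omits scaling; it is standard and
stabilizes training), residual + layer normalization, a position-wise FFN
with ReLU first layer, residual + normalization. A second, separately
parameterized encoder processes the scaffold-masked positions (whether the
two levels share weights was unstated; separate encoders are the more
expressive reading). Mean-pooled features of both sequences are
concatenated ("concatenated output") and drive a DNN head factorized as
P(position) × P(replacement | position); replacement logits score each
position's features against the library fragments' code embeddings, and
candidates whose attachment-point count cannot serve the position's bonds
are masked to exactly zero probability. Default architecture (all
configurable): L = 2 blocks, H = 4 heads, d_f = 64, d_p = 16, head width
64. The printed dimension of the output projection is read as
$(H d_p) \times d_f$.

**Training scope — a deliberate design decision.** The encoders and
embeddings are a *frozen, seeded random-feature representation*; A2C
updates train the position, replacement and critic MLP heads with
analytic gradients. Nothing in the method description fixes which
parameters the update touches, and hand-rolled backpropagation through a
full transformer (this package uses no autodiff framework) would add a
large defect surface for no observable benefit at desk scale. The
trade-off is honest: the forward pass implements the attention equations
exactly (oracle-checked to 1e-6), head gradients are finite-difference
checked, and the toy learning problems below are learnable through the
heads. A consequence worth knowing: tasks that require *reshaping the
state representation itself* (rather than re-weighting it) would train
slower than a fully backpropagated model.

**4. Reward.** A generated structure earns: 0 if it fails sanitization;
otherwise a validity term (default 0.1) plus, when property optimization
is enabled, 0.15 per in-range property, 0.2 when the whole gate passes,
and 0.3 when the activity oracle predicts active. The gate checks
inclusive bounds (MW 200–500 Da, logP 1.5–5.5, TPSA 40–120 Å², at most 2
toxicophore alerts — at most 2 being our reading of the 0–2 alert range).
The weights are invented defaults (none are published) and configurable;
the composition is monotone in each satisfied criterion. The toxicophore
screen ships as a small editable SMARTS list of common structural alerts
(nitro, nitroso, azo, acyl halide, aldehyde, epoxide/aziridine, hydrazine,
isocyanate, Michael-acceptor enone); no specific list is prescribed by the
method. Effectiveness E is interpreted as chemical validity with range
[1, 1]. Ligand efficiency has no published formula here; we define
LE = −score / heavy_atoms (the standard convention, the negation of the
perceptron's ratio feature) and gate it only when docking is enabled.
Activity prediction is a classic perceptron over three docking-derived
features (score, heavy-atom count, their ratio), trained on z-standardized
features with an IC50-style labeling supplied by the caller; on linearly
separable data it provably reaches 100% training accuracy.

**5. A2C loop.** One replacement per step, `Time` steps per episode (we
read "replacement count" as steps-per-episode; the alternative — several
fragments per single action — is less compatible with a per-step reward).
An invalid product earns reward 0 and the state reverts to the previous
valid state, so no stored state is ever invalid. Updates are synchronous,
single-worker, one-step TD:
$A = r + \gamma V(s')(1-\mathrm{done}) - V(s)$, actor loss
$-\overline{\log \pi \cdot A} - c\,H(\pi)$, critic loss the squared TD
error, one Adam step each. Defaults (invented, logged, configurable):
$\gamma = 0.99$, learning rates 3e-4, entropy coefficient 0.01, batch 32
episodes. "Dynamic parameter adjustment" is realized as a Time schedule:
fixed, or stepped up by one when the moving average of the gate-pass
fraction plateaus, since Time is the dial that trades similarity to the
seeds against novelty.

## Metrics

Validity, uniqueness and novelty compare canonical SMILES, not
fingerprints. Internal diversity is read as the power mean,
$\mathrm{IntDiv}_p = 1 - \left(\tfrac{1}{|G|^2}\sum_{m_1,m_2 \in G}
T(m_1,m_2)^p\right)^{1/p}$, with self-pairs included because the sum runs
over $G \times G$ literally; the no-self-pairs alternative cannot be ruled
out from the typesetting, and at benchmark set sizes the difference is
O(1/|G|). $T$ is Morgan-fingerprint (2048 bits, radius 2) Tanimoto —
the standard benchmark convention, configurable. Scaffold similarity is
the cosine of Bemis–Murcko scaffold frequency vectors over the union of
scaffolds; acyclic molecules contribute no scaffold, and two scaffold-free
sets score 0 with a warning. The Fréchet distance uses the symmetric
eigendecomposition square root with negative-eigenvalue clipping; its
default feature extractor is a *synthetic stand-in* (folded fingerprint
count bins plus scaled MW/logP/TPSA). Reproducing published FCD numbers
requires the trained ChemNet activations and is explicitly not claimed;
the extractor is pluggable for that purpose.

## Docking farm

The master/worker docking scheduler is modeled as a deterministic
work-queue executor: target-management and ligand-management roles plan a
cartesian task product, worker slots execute with bounded retries, and
every submitted task yields exactly one result. With a deterministic
engine the results are provably invariant to worker count — the contract
that makes the scheduling testable at desk scale. Real MPI deployment and
any bundled docking binary are out of scope; `command_engine()` is the
adapter seam. How per-ligand scores aggregate across target conformations
is unstated in the method; the reward layer takes a configurable
aggregator, defaulting to the best (most negative) score. The mock engine
is a pure seeded hash into [−12, −2], optionally biased by ligand size so
that activity is learnable in tests.

## The synthetic fixture world

`generate_fixtures()` composes molecules from a built-in catalog of ~66
ring cores, linkers and side chains, chosen so that (a) every part is
"cleavage-atomic" — fragmenting a generated molecule recovers exactly the
catalog parts, making library-level expectations computable by hand; (b)
MW, logP and TPSA straddle the default gate ranges (about 20% of medium
fixtures pass the full gate), so the reward surface has signal in both
directions; (c) a nitro side chain exercises the toxicophore screen. What
the fixtures do *not* emulate: realistic scaffold frequency
distributions, stereochemistry, charged species, macrocycles, or the
property distributions of any published compound corpus. A green test
therefore establishes algorithmic correctness and determinism, not
benchmark-level generation quality; the published benchmark numbers need
the external MOSES/GuacaMol corpora and long training runs, which are
deliberately out of desk-scale scope.

## Numerical choices and degenerate inputs

- Chemistry primitives (parsing, sanitization, descriptors, SMARTS,
  scaffolds, fingerprints, SA, QED, cleavage/reassembly) are delegated to
  RDKit through a bundled Python helper over a localhost socket, with a
  subprocess fallback and memoised vectorized wrappers. No chemistry is
  hand-rolled where RDKit provides it; everything algorithmic to this
  method (MCS, tree, policy, A2C, metrics formulas, farm) is implemented
  in R.
- Configuration is JSON (no YAML parser is available in the supported
  dependency set); unknown keys are rejected by name.
- Similarity ties in the tree and all stochastic components draw from
  explicit seeded streams derived from one root seed; repeated runs are
  byte-identical.
- A molecule with no ring atoms fragments to a single whole-molecule
  fragment; a single-fragment state has one replaceable position and an
  empty scaffold sequence (the scaffold pooled vector is zero).
- Surplus attachment points on an incoming replacement fragment are capped
  with hydrogen; attachment rewiring matches points in ascending index
  order.
- The learning-rate used by the toy-problem tests (0.02) differs from the
  package default (3e-4): toy bandits need larger steps; both are plain
  configuration.

## Known limitations

- The frozen-encoder policy (discussed above) trains heads only.
- MCS on pathological large fragments falls back to a lower bound when the
  expansion budget is exhausted (with a warning); fragment-sized inputs
  never hit the budget.
- The FCD stand-in extractor makes FCD values internally comparable but
  not comparable to published ChemNet-based numbers.
- Reassembly is not stereochemistry-aware, and no synthesizability
  constraint is enforced at assembly time (SA is reported, not gated, by
  default).
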