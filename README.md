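# fragrl

Fragment-based de novo molecular design with advantage actor-critic (A2C)
reinforcement learning, for computational chemists who want to optimize
lead compounds toward multi-objective property profiles while keeping the
scaffold chemistry of the starting set.

## What it does

Designing drug-like molecules means searching chemical space under several
constraints at once — physicochemical ranges, structural-alert avoidance,
and predicted bioactivity. fragrl frames this as a Markov decision process
over *fragment replacements*:

1. **Fragment library.** Input molecules are cleaved at every acyclic
   single bond extending from a ring atom, yielding ring systems, linkers
   and side chains with numbered attachment points (`fragment_molecule()`,
   `build_fragment_library()`).
2. **Similarity tree codes.** Fragment similarity is the Tanimoto
   coefficient over maximum-common-substructure atom counts,
   `TMCS(M1, M2) = mcs / (a(M1) + a(M2) - mcs)`. A similarity-driven
   balanced binary tree is built bottom-up (most similar pair first,
   single-linkage between subtrees); each fragment's binary code is its
   root-to-leaf path (left = "1", right = "0"), so similar fragments share
   prefixes (`pairwise_similarity()`, `build_balanced_tree()`).
3. **Transformer-DNN policy.** A molecule state — its ordered fragment
   sequence plus a scaffold-level sequence — is encoded by multi-head
   attention encoders; a DNN head outputs a joint distribution
   P(position) × P(replacement | position) over arity-compatible library
   fragments, alongside a critic value (`init_policy()`,
   `actor_forward()`, `critic_forward()`).
4. **Multi-objective reward.** Valid molecules earn a validity term plus
   bonuses for each property inside its inclusive target range
   (MW 200–500 Da, logP 1.5–5.5, TPSA 40–120 Å², ≤ 2 toxicophore alerts),
   a full-gate bonus, and an activity bonus from a perceptron over
   docking-derived features (score, heavy atoms, ratio). A deterministic
   master/worker docking-farm executor with a seeded mock engine supplies
   scores at desk scale (`total_reward()`, `train_perceptron()`,
   `run_farm()`).
5. **A2C training + metrics.** Episodes of `Time` replacements train the
   policy with one-step TD advantages (`train()`, `generate()`); generated
   sets are scored with validity, uniqueness, novelty, internal diversity
   IntDiv_p, Bemis–Murcko scaffold cosine similarity, a Fréchet distance
   over pluggable features, SA and QED (`generation_metrics()`).

Chemistry primitives are delegated to RDKit via a bundled Python helper
(persistent local socket server with subprocess fallback); the algorithms
above are implemented in R. See `vignettes/fragment-rl-methods.Rmd` for
the model, assumptions, and design decisions.

## Requirements and installation

Pre-installed requirements: R (≥ 4.1) with `jsonlite`, and a `python`
on `PATH` with RDKit importable (override via `options(fragrl.python=...)`
or `FRAGRL_PYTHON`).

```sh
R CMD INSTALL .
# test suite (includes the acceptance criteria):
Rscript -e 'testthat::test_dir("tests/testthat", package = "fragrl",
                               load_package = "installed")'
```

## Worked example

```r
library(fragrl)

fx   <- generate_fixtures(20, seed = 42)       # synthetic lead set
lib  <- build_fragment_library(fx$molecules)
sim  <- pairwise_similarity(lib)
tree <- build_balanced_tree(lib, sim)
lib
#> <fragment library> 38 fragments (linker: 12, ring: 17, side_chain: 9)
tree
#> <fragment tree> 38 leaves, max code length 6
tmcs_similarity("c1ccccc1", "Cc1ccccc1")
#> [1] 0.8571429        # 6 / (6 + 7 - 6): benzene inside toluene

cfg <- train_config(time = 1, epochs = 25, batch_size = 12, seed = 1,
                    lr_actor = 0.02, lr_critic = 0.02,
                    entropy_coef = 0.005)
fit <- train(fx$molecules[1:8], lib, tree, cfg = cfg,
             dims = policy_dims(H = 2, d_f = 16, d_p = 8, L = 1,
                                head_hidden = 32))
mean(fit$log$gate[1:5]); mean(fit$log$gate[21:25])
#> [1] 0.3166667       # property-gate pass fraction, first epochs
#> [1] 0.6             # ... and after training: the policy learned the gate

gen <- generate(fit$policy, fx$molecules[1:8], lib, tree,
                n = 40, time = 1, rng = rng_stream(5))
generation_metrics(gen, fx$molecules)
#> <generation metrics>
#>   validity   1.000
#>   uniqueness 0.225
#>   novelty    1.000
#>   intdiv     p1=0.756 p2=0.616
#>   scaff_sim  0.000
#>   fcd        18.286
#>   SA mean    2.16
#>   QED mean   0.768
```

Reading the numbers: every generated structure sanitizes (validity 1.0)
and none re-creates a training molecule (novelty 1.0); the trained policy
concentrates on rewarded replacements, so only 22.5% of the 40 samples are
distinct, and their scaffolds have moved away from the seed set
(scaffold cosine 0 against the reference). The FCD value uses the
package's synthetic stand-in feature extractor, so it is comparable only
across runs of this package, not to published ChemNet-based numbers. Mean
SA ≈ 2.2 (1 = easiest to synthesize) and mean QED ≈ 0.77 indicate
accessible, drug-like outputs.

## Command line

```sh
Rscript inst/scripts/fragrl fixtures --n 20 --seed 3 --out mols.smi
Rscript inst/scripts/fragrl fragment --input mols.smi --out library.json \
        --sim-matrix sim.csv
Rscript inst/scripts/fragrl tree     --library library.json --sim sim.csv \
        --out tree.json
Rscript inst/scripts/fragrl train    --input mols.smi --out runs/exp1 \
        --seed 17
Rscript inst/scripts/fragrl generate --checkpoint runs/exp1 \
        --input mols.smi --n 100 --time 1 --seed 17 --out gen.smi
Rscript inst/scripts/fragrl evaluate --gen gen.smi --ref mols.smi \
        --out metrics.json
Rscript inst/scripts/fragrl dock     --targets targets.txt \
        --ligands gen.smi --engine mock --workers 8 --out scores.csv
```

Every subcommand is seed-reproducible: the same `--seed` gives
byte-identical primary outputs.

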