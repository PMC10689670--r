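Package: fragrl
Title: Fragment-Based Molecular Generation with Actor-Critic Reinforcement Learning
Version: 0.1.0
Authors@R: person("fragrl", "developers", role = c("aut", "cre"),
    email = "fragrl@example.org")
Description: Tools for fragment-based de novo molecular design driven by
    advantage actor-critic (A2C) reinforcement learning. Molecules are cleaved
    at acyclic single bonds extending from ring atoms into rings, linkers and
    side chains; fragments are compared with a Tanimoto similarity over
    maximum-common-substructure atom counts and organized into a
    similarity-driven balanced binary tree whose root-to-leaf paths give each
    fragment a binary code. A transformer-encoder policy with a DNN head
    proposes fragment replacements, rewarded by a multi-objective
    physicochemical property gate, a toxicophore screen and a perceptron
    activity classifier over docking-derived features; a deterministic
    master/worker docking-farm executor with a seeded mock engine supplies
    docking scores. A full generation-metric suite (validity, uniqueness,
    novelty, internal diversity, Bemis-Murcko scaffold similarity, Frechet
    distance, SA, QED) evaluates generated sets. Chemistry primitives are
    delegated to RDKit through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit importable (used via a bundled
    helper script; interpreter configurable through option 'fragrl.python' or
    the FRAGRL_PYTHON environment variable)
Config/testthat/edition: 3
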