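# Shared fixtures, built once per test run and cached. Everything is
# generated in code; no data files.

.helpers <- new.env(parent = emptyenv())

helper_memo <- function(name, builder) {
  if (is.null(.helpers[[name]])) .helpers[[name]] <- builder()
  .helpers[[name]]
}

# small fixture world: 24 molecules, their library, similarities and tree
helper_world <- function() {
  helper_memo("world", function() {
    fx <- generate_fixtures(24, seed = 42)
    lib <- build_fragment_library(fx$molecules)
    sim <- pairwise_similarity(lib)
    tree <- build_balanced_tree(lib, sim)
    list(fx = fx, lib = lib, sim = sim, tree = tree)
  })
}

# large world: a 64-fragment library for the tree acceptance criterion
helper_lib64 <- function() {
  helper_memo("lib64", function() {
    fx <- generate_fixtures(150, seed = 202)
    lib <- build_fragment_library(fx$molecules)
    stopifnot(length(lib) >= 64L)
    lib$fragments <- lib$fragments[1:64]
    lib$index <- lib$index[1:64]
    sim <- pairwise_similarity(lib)
    list(lib = lib, sim = sim, molecules = fx$molecules)
  })
}

helper_tiny_policy <- function(world = helper_world(), seed = 1L) {
  init_policy(world$lib, world$tree,
              policy_dims(H = 2L, d_f = 16L, d_p = 8L, L = 1L,
                          head_hidden = 32L),
              seed = seed)
}
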