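test_that("fragment_molecule cleaves ring-extending single bonds", {
  # benzene: no eligible bond, returned whole
  b <- fragment_molecule("c1ccccc1")
  expect_length(b$fragments, 1L)
  expect_equal(b$fragments[[1]]$frag_class, "ring")
  expect_equal(b$fragments[[1]]$n_attach, 0L)

  # toluene: ring core + methyl side chain
  t <- fragment_molecule("Cc1ccccc1")
  expect_length(t$fragments, 2L)
  cls <- sort(vapply(t$fragments, `[[`, "", "frag_class"))
  expect_equal(cls, c("ring", "side_chain"))
  counts <- sort(vapply(t$fragments, `[[`, 1L, "atom_count"))
  expect_equal(counts, c(1L, 6L))

  # biphenyl: the inter-ring bond is eligible, two one-attachment rings
  bp <- fragment_molecule("c1ccc(-c2ccccc2)cc1")
  expect_length(bp$fragments, 2L)
  expect_true(all(vapply(bp$fragments, `[[`, "", "frag_class") == "ring"))
  expect_true(all(vapply(bp$fragments, `[[`, 1L, "n_attach") == 1L))

  expect_error(fragment_molecule("C1CC("), "cannot fragment")
})

test_that("decomposition map reassembles the input exactly", {
  world <- helper_world()
  for (smi in c("Cc1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
                world$fx$molecules[1:8])) {
    dec <- fragment_molecule(smi)
    job <- list(frags = vapply(dec$fragments, `[[`, "", "smiles"),
                bonds = dec$map$bonds)
    res <- fragrl:::chem_assemble_raw(list(job))[[1]]
    expect_true(res$ok)
    expect_identical(res$smiles, dec$canonical)
  }
})

test_that("library construction deduplicates by canonical structure", {
  lib <- build_fragment_library(c("Cc1ccccc1", "CCc1ccccc1"))
  # shared benzene core appears once: ring + methyl + ethyl
  expect_length(lib, 3L)
  expect_equal(sum(vapply(lib$fragments, `[[`, "", "frag_class") == "ring"),
               1L)
  # index is a bijection onto positions
  expect_equal(sort(unname(lib$index)), seq_along(lib$fragments))

  expect_length(build_fragment_library("c1ccccc1"), 1L)
  expect_error(build_fragment_library(character()))
  expect_error(build_fragment_library(c("xx(", "zz)")), "no input molecule")
  expect_warning(lib2 <- build_fragment_library(c("Cc1ccccc1", "xx(")),
                 "skipped")
  expect_length(lib2, 2L)
})

test_that("fragment invariants hold on the fixture library", {
  lib <- helper_world()$lib
  for (f in lib$fragments) {
    expect_gte(f$atom_count, 1L)
    # attachment placeholders numbered contiguously from 1
    maps <- as.integer(unlist(regmatches(
      f$smiles, gregexpr("(?<=\\*:)[0-9]+", f$smiles, perl = TRUE))))
    expect_setequal(maps, seq_len(f$n_attach))
    # canonicalization is idempotent
    expect_identical(chem_canonical(f$smiles), f$smiles)
    # ring class iff cyclic
    g <- fragrl:::chem_graph(f$smiles)[[1]]
    has_cycle <- length(g$bonds) >= length(g$atoms)
    expect_identical(f$frag_class == "ring", has_cycle)
  }
})

test_that("mcs_atom_count matches hand-derived cases", {
  expect_identical(mcs_atom_count("c1ccccc1", "c1ccccc1"), 6L)
  expect_identical(mcs_atom_count("c1ccc([*:1])cc1", "Cc1ccccc1"), 6L)
  expect_identical(mcs_atom_count("CC", "CCC"), 2L)
  expect_identical(mcs_atom_count("c1ccccc1", "C1CCCCC1"), 0L)
  # bounded by the smaller fragment
  expect_lte(mcs_atom_count("CCO", "CCCCO"), 3L)
})

test_that("tmcs_similarity implements the Tanimoto-MCS formula", {
  expect_equal(tmcs_similarity("c1ccccc1", "c1ccccc1"), 1.0)
  expect_equal(tmcs_similarity("c1ccccc1", "Cc1ccccc1"), 6 / 7)
  expect_equal(tmcs_similarity("CC", "OO"), 0.0)
  # symmetry on a handful of fixture pairs
  lib <- helper_world()$lib
  smis <- fragrl:::library_smiles(lib)[1:6]
  for (i in 1:5) {
    expect_equal(tmcs_similarity(smis[i], smis[i + 1]),
                 tmcs_similarity(smis[i + 1], smis[i]))
  }
})

test_that("pairwise_similarity equals per-pair recomputation", {
  world <- helper_world()
  sim <- world$sim
  expect_true(isSymmetric(unname(sim)))
  expect_equal(unname(diag(sim)), rep(1, length(world$lib)))
  expect_true(all(sim >= 0 & sim <= 1))
  smis <- fragrl:::library_smiles(world$lib)
  idx <- cbind(c(1, 2, 3, 5, 8), c(4, 7, 6, 9, 2))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    expect_equal(sim[i, j], tmcs_similarity(smis[i], smis[j]))
  }
  one <- build_fragment_library("c1ccccc1")
  expect_equal(unname(pairwise_similarity(one)), matrix(1, 1, 1))
})
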