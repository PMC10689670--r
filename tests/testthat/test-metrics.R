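test_that("validity, uniqueness and novelty fractions", {
  g <- c(rep("c1ccccc1", 9), "C1CC")
  expect_equal(validity_fraction(g), 0.9)
  expect_equal(validity_fraction(rep("C", 3)), 1.0)
  expect_equal(validity_fraction(rep("C1CC", 3)), 0.0)
  expect_error(validity_fraction(character()))

  expect_equal(uniqueness_fraction(c("c1ccccc1", "C1=CC=CC=C1")), 0.5)
  expect_equal(uniqueness_fraction(c("C", "CC", "CCC")), 1.0)
  expect_equal(uniqueness_fraction(rep("CCO", 4)), 0.25)

  expect_equal(novelty_fraction(c("C", "CC"), c("C", "CC")), 0.0)
  expect_equal(novelty_fraction(c("CCC", "CCCC"), c("C", "CC")), 1.0)
  expect_equal(novelty_fraction(c("C", "CCC"), c("C", "CC")), 0.5)
  # canonical comparison catches dialect differences
  expect_equal(novelty_fraction("C1=CC=CC=C1", "c1ccccc1"), 0.0)
})

test_that("internal diversity follows the power-mean identity", {
  # duplicate-only set: T == 1 everywhere, IntDiv = 0
  expect_equal(internal_diversity(rep("Cc1ccccc1", 5), p = 1), 0)
  expect_equal(internal_diversity(c("c1ccccc1", "C1=CC=CC=C1"), p = 2), 0)
  expect_equal(internal_diversity("CCO", p = 1), 0)
  # abstract two-element set with T = 0.5 (the hand example)
  tm <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(fragrl:::intdiv_from_tanimoto(tm, 1), 0.25)
  expect_equal(fragrl:::intdiv_from_tanimoto(tm, 2), 1 - sqrt(2.5 / 4))
  # brute-force double-loop equivalence on fixture molecules
  world <- helper_world()
  g <- world$fx$molecules[1:12]
  for (p in c(1, 2)) {
    expect_equal(internal_diversity(g, p), oracle_intdiv(g, p),
                 tolerance = 1e-12)
  }
})

test_that("scaffold similarity is a frequency cosine", {
  g <- c("Cc1ccccc1", "CCc1ccccc1")
  expect_equal(scaffold_similarity(g, g), 1.0)
  # disjoint scaffolds
  expect_equal(scaffold_similarity(g, c("CC1CCCCC1")), 0.0)
  # counts {benzene: 2} vs {benzene: 1, pyridine: 1}: cos = 2 / (2 sqrt 2)
  r <- c("Cc1ccccc1", "Cc1ccncc1")
  expect_equal(scaffold_similarity(g, r), 1 / sqrt(2))
  # invariant to ordering and to equal duplication
  expect_equal(scaffold_similarity(rev(g), r[c(2, 1)]),
               scaffold_similarity(g, r))
  expect_equal(scaffold_similarity(rep(g, 3), rep(r, 2)),
               scaffold_similarity(g, r))
  expect_warning(s0 <- scaffold_similarity("CC", "CCC"), "no scaffolds")
  expect_equal(s0, 0)
})

test_that("frechet distance matches scalar closed forms", {
  world <- helper_world()
  f <- fcd_features(world$fx$molecules[1:6])
  expect_equal(frechet_distance(f, f), 0, tolerance = 1e-8)
  # 1-D: mu diff 1, both variances 1 -> 1
  x <- matrix(c(-1, 1) / sqrt(2), 2, 1)
  expect_equal(frechet_distance(x, x + 1), 1, tolerance = 1e-8)
  # 1-D: equal means, variances 1 and 4 -> 1 + 4 - 2*2 = 1
  expect_equal(frechet_distance(x, 2 * x), 1, tolerance = 1e-8)
  # scalar closed form d^2 + s1^2 + s2^2 - 2 s1 s2 on random 1-D clouds
  rng <- rng_stream(23)
  a <- matrix(rng$rnorm(40, 1, 2), ncol = 1)
  b <- matrix(rng$rnorm(40, -0.5, 0.7), ncol = 1)
  closed <- (mean(a) - mean(b))^2 +
    stats::var(a[, 1]) + stats::var(b[, 1]) -
    2 * sqrt(stats::var(a[, 1]) * stats::var(b[, 1]))
  expect_equal(frechet_distance(a, b), closed, tolerance = 1e-8)
  # symmetry
  fa <- fcd_features(world$fx$molecules[1:5])
  fb <- fcd_features(world$fx$molecules[6:10])
  expect_equal(frechet_distance(fa, fb), frechet_distance(fb, fa),
               tolerance = 1e-8)
  expect_gt(frechet_distance(fa, fb), 0)
  expect_error(frechet_distance(matrix(NaN, 2, 2), matrix(0, 2, 2)),
               "non-finite")
})

test_that("SA and QED behave as published scores", {
  expect_true(all(sa_score(helper_world()$fx$molecules[1:5]) >= 1))
  expect_true(all(sa_score(helper_world()$fx$molecules[1:5]) <= 10))
  expect_lt(sa_score("c1ccccc1"), 3)
  expect_identical(sa_score("CCO"), sa_score("CCO"))
  q <- qed_score(c("CCO", "Cc1ccccc1"))
  expect_true(all(q >= 0 & q <= 1))
  # dialect invariance through canonicalization
  expect_equal(qed_score("C1=CC=CC=C1"), qed_score("c1ccccc1"))
  expect_error(sa_score("C1CC"), "invalid")
})

test_that("generation_metrics aggregates the full record", {
  world <- helper_world()
  g <- c(world$fx$molecules[1:8], "C1CC")
  m <- generation_metrics(g, world$fx$molecules[9:16])
  expect_s3_class(m, "fragrl_metrics")
  expect_equal(m$validity, 8 / 9)
  expect_true(m$uniqueness > 0 && m$uniqueness <= 1)
  expect_true(m$novelty >= 0 && m$novelty <= 1)
  expect_true(all(m$intdiv >= 0 & m$intdiv <= 1))
  expect_gte(m$fcd, 0)
  expect_output(print(m), "generation metrics")
})
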