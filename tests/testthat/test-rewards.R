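test_that("compute_properties returns standard descriptors", {
  p <- compute_properties("c1ccccc1")
  expect_identical(p$E, 1L)
  expect_equal(p$MW, 78.11, tolerance = 1e-3)
  expect_equal(p$PSA, 0)
  expect_identical(p$T, 0L)

  bad <- compute_properties("C1CC")
  expect_identical(bad$E, 0L)
  expect_true(is.na(bad$MW))

  nb <- compute_properties("O=[N+]([O-])c1ccccc1")
  expect_gte(nb$T, 1L)
})

test_that("toxicophore_count counts distinct matched patterns", {
  screen <- c("[N+](=O)[O-]", "C(=O)[F,Cl,Br,I]")
  expect_identical(toxicophore_count("c1ccccc1", character()), 0L)
  expect_identical(toxicophore_count("c1ccccc1", screen), 0L)
  expect_identical(toxicophore_count("O=[N+]([O-])c1ccccc1", screen), 1L)
  # two nitro groups still count one pattern
  expect_identical(
    toxicophore_count("O=[N+]([O-])c1ccc(cc1)[N+](=O)[O-]", screen), 1L)
  expect_error(toxicophore_count("c1ccccc1", "not-a-smarts"),
               "invalid SMARTS")
})

make_profile <- function(MW, logP, PSA, T) {
  structure(list(E = 1L, MW = MW, logP = logP, PSA = PSA, T = as.integer(T),
                 LE = NA_real_), class = "fragrl_profile")
}

test_that("property gate honors inclusive default ranges", {
  expect_true(property_gate(make_profile(300, 3.0, 80, 0)))
  expect_false(property_gate(make_profile(600, 3.0, 80, 0)))
  # bounds are inclusive
  expect_true(property_gate(make_profile(200, 1.5, 40, 2)))
  expect_true(property_gate(make_profile(500, 5.5, 120, 0)))
  expect_false(property_gate(make_profile(199.99, 3, 80, 0)))
  expect_false(property_gate(make_profile(300, 3, 80, 3)))
})

test_that("docking_features is exact arithmetic", {
  f <- docking_features(-8.0, 25L)
  expect_equal(f$ratio, -0.32)
  expect_equal(docking_features(0, 10L)$ratio, 0)
  expect_equal(docking_features(-6.3, 21L)$ratio, -0.3)
  expect_error(docking_features(-5, 0L), "heavy_atoms")
})

separable_set <- function(n = 200L, seed = 3L) {
  rng <- rng_stream(seed)
  act <- docking_features(rng$runif(n / 2, -11, -7.5),
                          as.integer(round(rng$runif(n / 2, 15, 35))))
  ina <- docking_features(rng$runif(n / 2, -4.5, -2),
                          as.integer(round(rng$runif(n / 2, 15, 35))))
  feats <- docking_features(c(act$score, ina$score),
                            c(act$heavy_atoms, ina$heavy_atoms))
  list(feats = feats, labels = rep(c(TRUE, FALSE), each = n / 2))
}

test_that("perceptron reaches perfect accuracy on separable data", {
  s <- separable_set()
  m <- train_perceptron(s$feats, s$labels, seed = 7)
  expect_equal(m$train_accuracy, 1.0)
  expect_identical(predict_activity(m, s$feats), s$labels)
  # label flip gives the mirror classifier
  m2 <- train_perceptron(s$feats, !s$labels, seed = 7)
  expect_equal(m2$train_accuracy, 1.0)
  expect_identical(predict_activity(m2, s$feats), !s$labels)
  # deterministic under seed
  m3 <- train_perceptron(s$feats, s$labels, seed = 7)
  expect_identical(m$weights, m3$weights)
  expect_error(train_perceptron(s$feats, rep(TRUE, 200)), "both classes")
})

test_that("total_reward decomposes and stays monotone", {
  w <- default_reward_weights()
  expect_equal(total_reward("C1CC")$total, 0)
  expect_equal(total_reward(NA_character_)$total, 0)
  # valid molecule failing every gate term: validity reward only
  r_small <- total_reward("C")   # methane: MW, logP, TPSA all out of range
  expect_equal(r_small$total, w$validity + 0.15 * 1)  # toxicophores in range
  # all-in-range molecule with forced-active oracle hits the configured max
  smi <- "CCOc1ccc(CC(=O)Nc2ccc(F)cc2)cc1"  # MW ~ 317, logP ~ 3, TPSA ~ 38?
  prof <- compute_properties(smi)
  r <- total_reward(smi, activity_fn = function(s) TRUE)
  expect_equal(r$gate_pass, property_gate(prof))
  if (r$gate_pass) {
    expect_equal(r$total,
                 w$validity + 4 * w$property + w$gate + w$activity)
  }
  # monotonicity over random profiles: widening satisfied range set never
  # lowers the reward (checked structurally via the weights)
  rng <- rng_stream(17)
  for (i in 1:50) {
    mw <- rng$runif(1, 100, 700)
    ranges1 <- default_property_ranges()
    ranges2 <- ranges1; ranges2$MW <- c(0, 1000)  # strictly easier gate
    r1 <- total_reward("Cc1ccccc1", ranges = ranges1)
    r2 <- total_reward("Cc1ccccc1", ranges = ranges2)
    expect_gte(r2$total, r1$total)
  }
})

test_that("ablation switch strips property and activity terms", {
  r <- total_reward("Cc1ccccc1", activity_fn = function(s) TRUE,
                    use_property_optimization = FALSE)
  expect_equal(r$property_reward, 0)
  expect_equal(r$activity_reward, 0)
  expect_equal(r$total, default_reward_weights()$validity)
})
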