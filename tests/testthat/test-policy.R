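test_that("transformer block matches hand-set single-head arithmetic", {
  set.seed(99)
  d_f <- 4L; d_p <- 2L
  blk <- list(
    heads = list(list(Wq = matrix(rnorm(8), d_f, d_p),
                      Wk = matrix(rnorm(8), d_f, d_p),
                      Wv = matrix(rnorm(8), d_f, d_p))),
    Wo = matrix(rnorm(8), d_p, d_f),
    ln1_g = c(1, 0.5, 2, 1), ln1_b = c(0, 0.1, -0.1, 0),
    W1 = matrix(rnorm(8 * 4), d_f, 8L), b1 = rnorm(8),
    W2 = matrix(rnorm(8 * 4), 8L, d_f), b2 = rnorm(4),
    ln2_g = rep(1, 4), ln2_b = rep(0, 4))
  x <- matrix(rnorm(8), 2L, d_f)
  enc <- transformer_encode(x, list(blocks = list(blk)))
  expect_equal(enc$out, oracle_transformer_block(x, blk), tolerance = 1e-6)
  # attention rows are normalized
  expect_equal(rowSums(enc$attn[[1]][[1]]), c(1, 1), tolerance = 1e-9)
})

test_that("single-token attention returns that token's value projection", {
  set.seed(7)
  Wq <- matrix(rnorm(8), 4, 2); Wk <- matrix(rnorm(8), 4, 2)
  Wv <- matrix(rnorm(8), 4, 2)
  x <- matrix(rnorm(4), 1, 4)
  head <- fragrl:::nn_attention_head(x, x, Wq, Wk, Wv)
  expect_equal(head$out, x %*% Wv)
  expect_equal(as.numeric(head$weights), 1)
})

test_that("embed_state shapes and determinism", {
  world <- helper_world()
  pol <- helper_tiny_policy(world)
  st <- decompose(world$fx$molecules[1], world$lib)
  emb <- embed_state(st, world$tree, pol)
  expect_identical(nrow(emb$fragment_tokens), length(st$fragments))
  expect_identical(nrow(emb$scaffold_tokens), sum(st$scaffold_mask))
  expect_identical(ncol(emb$fragment_tokens), pol$dims$d_f)
  pol2 <- helper_tiny_policy(world)
  expect_identical(embed_state(st, world$tree, pol2), emb)
})

test_that("actor distributions are normalized, masked and deterministic", {
  world <- helper_world()
  pol <- helper_tiny_policy(world)
  for (smi in world$fx$molecules[1:4]) {
    st <- decompose(smi, world$lib)
    d <- actor_forward(st, world$tree, pol)
    expect_equal(sum(d$position_probs), 1, tolerance = 1e-6)
    expect_equal(unname(rowSums(d$replacement_probs)),
                 rep(1, length(st$fragments)), tolerance = 1e-6)
    expect_true(all(is.finite(d$position_probs)))
    # arity-incompatible candidates carry exactly zero mass
    expect_true(all(d$replacement_probs[!d$mask] == 0))
    need <- vapply(seq_along(st$fragments), function(i) {
      length(fragrl:::bonds_at_position(st, i))
    }, integer(1))
    arity <- vapply(world$lib$fragments, `[[`, 1L, "n_attach")
    expect_identical(d$mask, outer(need, arity, `<=`))
    d2 <- actor_forward(st, world$tree, pol)
    expect_identical(d2$position_probs, d$position_probs)
  }
})

test_that("critic is finite and deterministic", {
  world <- helper_world()
  pol <- helper_tiny_policy(world)
  vals <- vapply(world$fx$molecules[1:5], function(smi) {
    critic_forward(decompose(smi, world$lib), world$tree, pol)
  }, numeric(1))
  expect_true(all(is.finite(vals)))
  expect_identical(critic_forward(decompose(world$fx$molecules[1],
                                            world$lib),
                                  world$tree, pol), vals[[1]])
})

test_that("sample_action is reproducible and frequency-consistent", {
  world <- helper_world()
  pol <- helper_tiny_policy(world)
  st <- decompose(world$fx$molecules[2], world$lib)
  d <- actor_forward(st, world$tree, pol)
  a1 <- sample_action(d, rng_stream(5))
  a2 <- sample_action(d, rng_stream(5))
  expect_identical(a1, a2)
  # point mass
  dp <- d
  dp$position_probs <- as.numeric(seq_along(d$position_probs) == 2L)
  k0 <- which(d$replacement_probs[2, ] > 0)[1]
  dp$replacement_probs[2, ] <- as.numeric(
    seq_len(ncol(d$replacement_probs)) == k0)
  ap <- sample_action(dp, rng_stream(1))
  expect_identical(ap, list(position = 2L, replacement = k0))
  # binomial 3-sigma bound on a known two-point position distribution
  db <- d
  db$position_probs <- c(0.3, 0.7, rep(0, length(d$position_probs) - 2L))
  rng <- rng_stream(11)
  n <- 10000L
  hits <- sum(vapply(seq_len(n), function(i) {
    sample_action(db, rng)$position == 1L
  }, logical(1)))
  expect_lt(abs(hits / n - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("analytic head gradients agree with finite differences", {
  world <- helper_world()
  pol <- helper_tiny_policy(world)
  st <- decompose(world$fx$molecules[3], world$lib)
  tree <- world$tree
  d0 <- actor_forward(st, tree, pol)
  action <- list(position = 1L,
                 replacement = which(d0$replacement_probs[1, ] > 0)[1])
  adv <- 0.7; ec <- 0.05
  loss_fn <- function(p) {
    d <- actor_forward(st, tree, p)
    pp <- d$position_probs; P <- d$replacement_probs
    rowH <- apply(P, 1, function(q) { q <- q[q > 0]; -sum(q * log(q)) })
    Hjoint <- -sum(pp[pp > 0] * log(pp[pp > 0])) + sum(pp * rowH)
    -adv * (log(pp[action$position]) +
              log(P[action$position, action$replacement])) - ec * Hjoint
  }
  g <- fragrl:::actor_grads(d0, action, adv, ec, pol)
  eps <- 1e-5
  for (head in c("pos", "repl")) {
    for (par in c("W1", "b1")) {
      for (idx in c(1L, 5L, 17L)) {
        p2 <- pol; p2$heads[[head]][[par]][idx] <-
          p2$heads[[head]][[par]][idx] + eps
        p3 <- pol; p3$heads[[head]][[par]][idx] <-
          p3$heads[[head]][[par]][idx] - eps
        num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
        expect_equal(g[[head]][[par]][idx], num, tolerance = 1e-4)
      }
    }
  }
  # critic gradient
  target <- 0.9
  gc <- fragrl:::critic_grads(st, tree, pol, target)
  closs <- function(p) (target - critic_forward(st, tree, p))^2
  for (idx in c(1L, 9L, 23L)) {
    p2 <- pol; p2$heads$critic$W1[idx] <- p2$heads$critic$W1[idx] + eps
    p3 <- pol; p3$heads$critic$W1[idx] <- p3$heads$critic$W1[idx] - eps
    expect_equal(gc$grads$W1[idx], (closs(p2) - closs(p3)) / (2 * eps),
                 tolerance = 1e-4)
  }
})
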