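#' @name policy
#' @title Transformer-DNN actor and critic
#'
#' @description
#' The policy maps a molecule state to a joint distribution over
#' (position to replace, replacement fragment) and a scalar state value.
#' Each fragment token is the sum of a code embedding (the fragment's tree
#' bit-code, padded to a fixed length with a pad symbol) and a learned
#' position embedding. Two separate transformer encoders process the
#' fragment-level sequence and the scaffold-level sequence (the
#' scaffold-masked positions only); attention logits are scaled by
#' `sqrt(d_p)`. Mean-pooled features of both sequences are concatenated and,
#' together with each position's encoded feature, drive three MLP heads:
#' a position head, a per-position replacement head scored against library
#' fragment code embeddings, and the critic value head. Replacement
#' candidates whose attachment-point count cannot serve the outgoing
#' fragment's bonds are masked to exactly zero probability.
#'
#' The encoders and embeddings are a fixed random-feature representation
#' (seeded at initialization); A2C training updates the three MLP heads
#' analytically. See the methods vignette for the rationale.
NULL

#' Default policy dimensions
#' @return list of architecture hyperparameters
#' @export
policy_dims <- function(H = 4L, d_f = 64L, d_p = 16L, L = 2L,
                        d_ff = 4L * d_f, head_hidden = 64L,
                        max_positions = 32L) {
  list(H = as.integer(H), d_f = as.integer(d_f), d_p = as.integer(d_p),
       L = as.integer(L), d_ff = as.integer(d_ff),
       head_hidden = as.integer(head_hidden),
       max_positions = as.integer(max_positions))
}

#' Initialize transformer-DNN policy parameters
#'
#' @param lib a `fragrl_library`
#' @param tree the `fragrl_tree` over `lib`
#' @param dims from [policy_dims()]
#' @param seed integer seed for the initialization stream
#' @return a `fragrl_policy` parameter object
#' @export
init_policy <- function(lib, tree, dims = policy_dims(), seed = 1L) {
  stopifnot(inherits(lib, "fragrl_library"), inherits(tree, "fragrl_tree"))
  rng <- rng_stream(seed)$derive(101)
  code_len <- max(1L, max(nchar(tree$codes)))
  init_encoder <- function() {
    list(code_emb = array(rng$rnorm(3 * code_len * dims$d_f, 0, 0.3),
                          dim = c(3, code_len, dims$d_f)),
         pos_emb = nn_init_matrix(rng, dims$max_positions, dims$d_f, 0.3),
         blocks = lapply(seq_len(dims$L), function(i) {
           nn_init_block(rng, dims$d_f, dims$d_p, dims$H, dims$d_ff)
         }))
  }
  frag_enc <- init_encoder()
  scaf_enc <- init_encoder()
  hp <- dims$head_hidden
  heads <- list(
    pos = list(W1 = nn_init_matrix(rng, 3 * dims$d_f, hp), b1 = rep(0, hp),
               w2 = nn_init_matrix(rng, hp, 1), b2 = 0),
    repl = list(W1 = nn_init_matrix(rng, 3 * dims$d_f, hp), b1 = rep(0, hp),
                W2 = nn_init_matrix(rng, hp, dims$d_f),
                b2 = rep(0, dims$d_f)),
    critic = list(W1 = nn_init_matrix(rng, 2 * dims$d_f, hp),
                  b1 = rep(0, hp),
                  w2 = nn_init_matrix(rng, hp, 1), b2 = 0))
  # frozen library fragment representations from their tree codes
  G <- t(vapply(seq_len(tree$n_leaves), function(i) {
    embed_code(tree$codes[i], frag_enc$code_emb, code_len)
  }, numeric(dims$d_f)))
  structure(list(dims = dims, code_len = code_len,
                 frag_enc = frag_enc, scaf_enc = scaf_enc,
                 heads = heads, G = G,
                 lib_arity = vapply(lib$fragments, `[[`, integer(1),
                                    "n_attach"),
                 cache = new.env(parent = emptyenv())),
            class = "fragrl_policy")
}

#' @export
print.fragrl_policy <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "<policy> L=%d blocks, H=%d heads, d_f=%d, d_p=%d, %d library fragments\n",
    d$L, d$H, d$d_f, d$d_p, nrow(x$G)))
  invisible(x)
}

# code string -> d_f vector: sum of per-slot symbol embeddings
# symbols: "0" -> 1, "1" -> 2, pad -> 3
embed_code <- function(code, code_emb, code_len) {
  syms <- rep(3L, code_len)
  if (nchar(code) > 0L) {
    bits <- strsplit(code, "")[[1]]
    if (length(bits) > code_len) stop("code longer than embedding length")
    syms[seq_along(bits)] <- ifelse(bits == "1", 2L, 1L)
  }
  out <- numeric(dim(code_emb)[3])
  for (j in seq_len(code_len)) out <- out + code_emb[syms[j], j, ]
  out
}

#' Embed a molecule state into token sequences
#'
#' @param state a `fragrl_state`
#' @param tree the `fragrl_tree` providing fragment codes
#' @param policy a `fragrl_policy`
#' @return list with `fragment_tokens` (n x d_f) and `scaffold_tokens`
#'   (scaffold positions only; 0-row matrix when the state has none)
#' @export
embed_state <- function(state, tree, policy) {
  n <- length(state$fragments)
  if (n > policy$dims$max_positions) {
    stop("state has more fragments than max_positions")
  }
  codes <- tree$codes[state$fragments]
  tok <- t(vapply(seq_len(n), function(i) {
    embed_code(codes[i], policy$frag_enc$code_emb, policy$code_len) +
      policy$frag_enc$pos_emb[i, ]
  }, numeric(policy$dims$d_f)))
  sidx <- which(state$scaffold_mask)
  stok <- if (length(sidx) > 0L) {
    t(vapply(sidx, function(i) {
      embed_code(codes[i], policy$scaf_enc$code_emb, policy$code_len) +
        policy$scaf_enc$pos_emb[i, ]
    }, numeric(policy$dims$d_f)))
  } else {
    matrix(0, 0, policy$dims$d_f)
  }
  list(fragment_tokens = tok, scaffold_tokens = stok)
}

#' Run the transformer encoder over a token sequence
#'
#' Per block: multi-head scaled-dot-product attention with per-head
#' projections, concatenation and output projection; residual + layer norm;
#' position-wise FFN with ReLU first layer; residual + layer norm.
#'
#' @param tokens numeric matrix (positions x d_f)
#' @param encoder one of `policy$frag_enc` / `policy$scaf_enc`, or any list
#'   with a `blocks` element in the same shape
#' @return list with `out` (encoded features) and `attn` (per-block,
#'   per-head attention weight matrices)
#' @export
transformer_encode <- function(tokens, encoder) {
  nn_encoder(tokens, encoder)
}

state_key <- function(state) {
  paste(paste(state$fragments, collapse = ","),
        paste(as.integer(state$scaffold_mask), collapse = ""),
        sep = "|")
}

# frozen-encoder features, memoised per state
policy_features <- function(state, tree, policy) {
  key <- state_key(state)
  hit <- get0(key, envir = policy$cache)
  if (!is.null(hit)) return(hit)
  emb <- embed_state(state, tree, policy)
  enc_f <- transformer_encode(emb$fragment_tokens, policy$frag_enc)$out
  pooled_f <- colMeans(enc_f)
  pooled_s <- if (nrow(emb$scaffold_tokens) > 0L) {
    colMeans(transformer_encode(emb$scaffold_tokens, policy$scaf_enc)$out)
  } else {
    numeric(policy$dims$d_f)
  }
  pooled <- c(pooled_f, pooled_s)
  n <- nrow(enc_f)
  U <- cbind(enc_f, matrix(pooled, n, length(pooled), byrow = TRUE))
  res <- list(U = U, pooled = pooled)
  assign(key, res, envir = policy$cache)
  res
}

# arity mask: candidate k allowed at position i iff it has at least as many
# attachment points as the position has bonds
arity_mask <- function(state, policy) {
  need <- vapply(seq_along(state$fragments), function(i) {
    length(bonds_at_position(state, i))
  }, integer(1))
  outer(need, policy$lib_arity, `<=`)
}

#' Actor forward pass
#'
#' @param state a `fragrl_state` with at least one replaceable position
#' @param tree the `fragrl_tree`
#' @param policy a `fragrl_policy`
#' @return a `fragrl_action_dist`: `position_probs` (length n),
#'   `replacement_probs` (n x library size, masked entries exactly 0), and
#'   a forward cache used by the A2C update
#' @export
actor_forward <- function(state, tree, policy) {
  if (length(state$fragments) < 1L) stop("degenerate state: no positions")
  ft <- policy_features(state, tree, policy)
  hp <- policy$heads
  H1p <- nn_relu(sweep(ft$U %*% hp$pos$W1, 2, hp$pos$b1, "+"))
  pos_logits <- as.vector(H1p %*% hp$pos$w2) + hp$pos$b2
  position_probs <- nn_softmax(pos_logits)
  H1r <- nn_relu(sweep(ft$U %*% hp$repl$W1, 2, hp$repl$b1, "+"))
  Hrep <- sweep(H1r %*% hp$repl$W2, 2, hp$repl$b2, "+")
  repl_logits <- Hrep %*% t(policy$G)
  mask <- arity_mask(state, policy)
  repl_logits[!mask] <- -Inf
  replacement_probs <- nn_softmax_rows(repl_logits)
  structure(list(position_probs = position_probs,
                 replacement_probs = replacement_probs,
                 mask = mask,
                 cache = list(U = ft$U, pooled = ft$pooled,
                              H1p = H1p, H1r = H1r, Hrep = Hrep)),
            class = "fragrl_action_dist")
}

#' Critic forward pass
#'
#' @inheritParams actor_forward
#' @return scalar state-value estimate
#' @export
critic_forward <- function(state, tree, policy) {
  ft <- policy_features(state, tree, policy)
  hc <- policy$heads$critic
  x <- matrix(ft$pooled, 1)
  h <- nn_relu(sweep(x %*% hc$W1, 2, hc$b1, "+"))
  as.vector(h %*% hc$w2) + hc$b2
}

#' Sample an action from an action distribution
#'
#' @param dist a `fragrl_action_dist`
#' @param rng a stream from [rng_stream()]
#' @return list(position, replacement)
#' @export
sample_action <- function(dist, rng) {
  i <- rng$sample_prob(dist$position_probs)
  k <- rng$sample_prob(dist$replacement_probs[i, ])
  list(position = i, replacement = k)
}

# ---- analytic gradients for the heads -------------------------------------

# gradient of the actor objective for one transition:
#   L = -advantage * log pi(a|s) - entropy_coef * H(joint)
# returns grads shaped like policy$heads[c("pos","repl")]
actor_grads <- function(dist, action, advantage, entropy_coef, policy) {
  p <- dist$position_probs
  P <- dist$replacement_probs
  n <- length(p)
  cache <- dist$cache
  # per-position replacement entropies (masked zeros contribute nothing)
  rowH <- apply(P, 1, function(q) {
    q <- q[q > 0]; -sum(q * log(q))
  })
  Hpos <- -sum(p[p > 0] * log(p[p > 0]))
  Hbar <- sum(p * rowH)
  # d L / d position logits
  d_pos <- -advantage * ((seq_len(n) == action$position) - p)
  d_pos <- d_pos - entropy_coef *
    (-p * (ifelse(p > 0, log(pmax(p, 1e-300)), 0) + Hpos) +
       p * (rowH - Hbar))
  # d L / d replacement logits (masked entries stay zero)
  dY <- matrix(0, n, ncol(P))
  i <- action$position
  dY[i, ] <- -advantage * ((seq_len(ncol(P)) == action$replacement) - P[i, ])
  logP <- ifelse(P > 0, log(pmax(P, 1e-300)), 0)
  dY <- dY + entropy_coef * (p * P * (logP + rowH))
  dY[!dist$mask] <- 0
  # backprop heads
  hp <- policy$heads
  # position head: logits = relu(U W1 + b1) w2 + b2
  dH1p <- (matrix(d_pos, ncol = 1) %*% t(hp$pos$w2)) * (cache$H1p > 0)
  g_pos <- list(W1 = t(cache$U) %*% dH1p, b1 = colSums(dH1p),
                w2 = t(cache$H1p) %*% matrix(d_pos, ncol = 1),
                b2 = sum(d_pos))
  # replacement head: Y = (relu(U W1 + b1) W2 + b2) G^T
  dHrep <- dY %*% policy$G
  dH1r <- (dHrep %*% t(hp$repl$W2)) * (cache$H1r > 0)
  g_repl <- list(W1 = t(cache$U) %*% dH1r, b1 = colSums(dH1r),
                 W2 = t(cache$H1r) %*% dHrep, b2 = colSums(dHrep))
  list(pos = g_pos, repl = g_repl)
}

# gradient of (target - V)^2 w.r.t. critic head params
critic_grads <- function(state, tree, policy, target) {
  ft <- policy_features(state, tree, policy)
  hc <- policy$heads$critic
  x <- matrix(ft$pooled, 1)
  pre <- sweep(x %*% hc$W1, 2, hc$b1, "+")
  h <- nn_relu(pre)
  v <- as.vector(h %*% hc$w2) + hc$b2
  dv <- -2 * (target - v)
  dh <- (dv * t(hc$w2)) * (pre > 0)
  list(grads = list(W1 = t(x) %*% dh, b1 = as.vector(dh),
                    w2 = t(h) * dv, b2 = dv),
       value = v, loss = (target - v)^2)
}
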