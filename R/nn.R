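# Dense neural-network primitives for the transformer policy. Plain base-R
# matrix arithmetic throughout; shapes follow the sequence-major convention
# (rows = sequence positions, columns = features).

nn_relu <- function(x) pmax(x, 0)

# numerically stable row-wise softmax; -Inf entries get exactly zero mass
nn_softmax_rows <- function(z) {
  z <- as.matrix(z)
  out <- matrix(0, nrow(z), ncol(z))
  for (i in seq_len(nrow(z))) {
    zi <- z[i, ]
    finite <- is.finite(zi)
    if (!any(finite)) stop("softmax over fully masked logits")
    e <- exp(zi[finite] - max(zi[finite]))
    out[i, finite] <- e / sum(e)
  }
  out
}

nn_softmax <- function(z) as.vector(nn_softmax_rows(matrix(z, nrow = 1)))

# row-wise layer normalization with learned gain/bias
nn_layer_norm <- function(x, gamma, beta, eps = 1e-6) {
  mu <- rowMeans(x)
  v <- rowMeans((x - mu)^2)
  ((x - mu) / sqrt(v + eps)) * rep(gamma, each = nrow(x)) +
    rep(beta, each = nrow(x))
}

# one attention head: queries from xq, keys/values from xkv; logits scaled
# by sqrt(d_p)
nn_attention_head <- function(xq, xkv, Wq, Wk, Wv) {
  q <- xq %*% Wq
  k <- xkv %*% Wk
  v <- xkv %*% Wv
  logits <- (q %*% t(k)) / sqrt(ncol(Wq))
  weights <- nn_softmax_rows(logits)
  list(out = weights %*% v, weights = weights)
}

# multi-head attention + output projection (concatenated heads times W_O)
nn_multi_head <- function(xq, xkv, block) {
  heads <- lapply(block$heads, function(h) {
    nn_attention_head(xq, xkv, h$Wq, h$Wk, h$Wv)
  })
  concat <- do.call(cbind, lapply(heads, `[[`, "out"))
  list(out = concat %*% block$Wo,
       attn = lapply(heads, `[[`, "weights"))
}

# one encoder block: multi-head attention, residual + layer norm,
# position-wise FFN (ReLU first layer), residual + layer norm
nn_encoder_block <- function(x, block) {
  mh <- nn_multi_head(x, x, block)
  h <- nn_layer_norm(x + mh$out, block$ln1_g, block$ln1_b)
  ffn <- nn_relu(sweep(h %*% block$W1, 2, block$b1, "+")) %*% block$W2
  ffn <- sweep(ffn, 2, block$b2, "+")
  list(out = nn_layer_norm(h + ffn, block$ln2_g, block$ln2_b),
       attn = mh$attn)
}

# full encoder stack; returns features plus per-block attention maps
nn_encoder <- function(tokens, enc) {
  if (nrow(tokens) == 0L) stop("empty token sequence")
  x <- tokens
  attn <- list()
  for (b in enc$blocks) {
    step <- nn_encoder_block(x, b)
    x <- step$out
    attn[[length(attn) + 1L]] <- step$attn
  }
  list(out = x, attn = attn)
}

nn_init_matrix <- function(rng, nr, nc, sd = 0.08) {
  matrix(rng$rnorm(nr * nc, 0, sd), nr, nc)
}

nn_init_block <- function(rng, d_f, d_p, H, d_ff) {
  list(
    heads = lapply(seq_len(H), function(h) {
      list(Wq = nn_init_matrix(rng, d_f, d_p),
           Wk = nn_init_matrix(rng, d_f, d_p),
           Wv = nn_init_matrix(rng, d_f, d_p))
    }),
    Wo = nn_init_matrix(rng, H * d_p, d_f),
    ln1_g = rep(1, d_f), ln1_b = rep(0, d_f),
    W1 = nn_init_matrix(rng, d_f, d_ff), b1 = rep(0, d_ff),
    W2 = nn_init_matrix(rng, d_ff, d_f), b2 = rep(0, d_f),
    ln2_g = rep(1, d_f), ln2_b = rep(0, d_f))
}

# ---- Adam optimizer over nested lists of numeric arrays -------------------

adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) return(lapply(p, walk))
    list(m = p * 0, v = p * 0)
  }
  list(state = lapply(params, walk), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  t <- opt$t
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (nm in names(p)) {
        res <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- res$p; out_s[[nm]] <- res$s
      }
      return(list(p = out_p, s = out_s))
    }
    if (any(!is.finite(g))) stop("non-finite gradient encountered")
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  res <- walk(params, grads, opt$state)
  list(params = res$p, opt = list(state = res$s, t = t))
}

# elementwise sum / scale of nested grad lists
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) return(mapply(grads_add, a, b, SIMPLIFY = FALSE))
  a + b
}

grads_scale <- function(a, f) {
  if (is.list(a)) return(lapply(a, grads_scale, f = f))
  a * f
}
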