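# Independent oracles, deliberately written with different algorithms than
# the implementation they check.

# Brute-force connected-MCS size: enumerate every connected vertex subset of
# the smaller graph (bitmask enumeration), largest first, and search for a
# label-preserving injection into the other graph whose common-edge graph
# spans and connects the subset. No bound pruning, no shared code with
# mcs_size().
oracle_mcs_size <- function(g1, g2) {
  if (g1$n > g2$n) { tmp <- g1; g1 <- g2; g2 <- tmp }
  n1 <- g1$n
  if (n1 == 0L || g2$n == 0L) return(0L)
  stopifnot(n1 <= 16L)
  connected_in <- function(vs, amat) {
    if (length(vs) == 1L) return(TRUE)
    seen <- vs[1]
    frontier <- vs[1]
    while (length(frontier) > 0L) {
      nxt <- setdiff(vs[colSums(amat[frontier, vs, drop = FALSE]) > 0], seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    length(seen) == length(vs)
  }
  # all connected subsets of g1, grouped by size
  subsets <- vector("list", n1)
  for (mask in seq_len(2^n1 - 1L)) {
    vs <- which(bitwAnd(mask, 2^(seq_len(n1) - 1L)) > 0)
    if (connected_in(vs, g1$amat)) {
      k <- length(vs)
      subsets[[k]] <- c(subsets[[k]], list(vs))
    }
  }
  embeds <- function(vs) {
    k <- length(vs)
    # enumerate injective, label-preserving assignments
    assign_next <- function(pos, img) {
      if (pos > k) {
        # common-edge graph must connect vs
        common <- matrix(FALSE, k, k)
        for (a in seq_len(k)) {
          for (b in seq_len(k)) {
            common[a, b] <- g1$amat[vs[a], vs[b]] && g2$amat[img[a], img[b]]
          }
        }
        return(connected_in(seq_len(k), common))
      }
      for (j in setdiff(which(g2$labels == g1$labels[vs[pos]]), img)) {
        if (assign_next(pos + 1L, c(img, j))) return(TRUE)
      }
      FALSE
    }
    assign_next(1L, integer())
  }
  for (k in rev(seq_len(n1))) {
    for (vs in subsets[[k]] %||% list()) {
      if (embeds(vs)) return(k)
    }
  }
  0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force double-loop internal diversity from explicit fingerprints
oracle_intdiv <- function(smiles, p) {
  fps <- fragrl:::chem_fingerprint(chem_canonical(smiles))
  n <- length(fps)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      inter <- length(intersect(fps[[i]], fps[[j]]))
      uni <- length(union(fps[[i]], fps[[j]]))
      t <- if (uni == 0L) 0 else inter / uni
      acc <- acc + t^p
    }
  }
  1 - (acc / n^2)^(1 / p)
}

# step-by-step transformer block on a 2-token input with single-head
# parameters; plain arithmetic, no shared helpers
oracle_transformer_block <- function(x, blk) {
  q <- x %*% blk$heads[[1]]$Wq
  k <- x %*% blk$heads[[1]]$Wk
  v <- x %*% blk$heads[[1]]$Wv
  scores <- q %*% t(k) / sqrt(ncol(q))
  w <- t(apply(scores, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  a <- w %*% v
  mh <- a %*% blk$Wo
  h1 <- x + mh
  ln <- function(z, g, b) {
    t(apply(z, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-6) * g + b
    }))
  }
  h1 <- ln(h1, blk$ln1_g, blk$ln1_b)
  ffn <- pmax(h1 %*% blk$W1 + matrix(blk$b1, nrow(h1), length(blk$b1),
                                     byrow = TRUE), 0) %*% blk$W2 +
    matrix(blk$b2, nrow(h1), length(blk$b2), byrow = TRUE)
  ln(h1 + ffn, blk$ln2_g, blk$ln2_b)
}
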