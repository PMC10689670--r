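#' @name fragment_tree
#' @title Similarity-driven balanced binary tree encoding
#'
#' @description
#' Fragments are consolidated bottom-up into a balanced binary tree: in each
#' pairing round the two most similar trees are merged repeatedly until at
#' most one unpaired tree remains, and rounds continue until a single tree
#' holds every fragment. Inter-tree similarity is the highest TMCS between
#' any two member fragments (single linkage). Each fragment's binary code is
#' its root-to-leaf path, appending "1" for a left branch and "0" for a
#' right branch, so similar fragments share code prefixes.
#'
#' Determinism: similarities are compared with an absolute tolerance of
#' 1e-12; ties prefer the pair with the lexicographically smallest
#' (min index, max index); within a merge the operand containing the smaller
#' minimum library index becomes the left child; an odd leftover tree is
#' promoted unchanged to the next round.
NULL

new_tree_node <- function(node_id, fragment_ref = NULL, left = NULL,
                          right = NULL, members) {
  list(node_id = node_id, fragment_ref = fragment_ref,
       left = left, right = right, members = members)
}

#' Build the balanced binary fragment tree
#'
#' @param lib a `fragrl_library`
#' @param sim symmetric TMCS similarity matrix from [pairwise_similarity()]
#' @return a `fragrl_tree`: list with `root` (nested node records), `codes`
#'   (character vector, one bit-string per library fragment) and `n_leaves`
#' @export
build_balanced_tree <- function(lib, sim) {
  stopifnot(inherits(lib, "fragrl_library"))
  n <- length(lib)
  if (!is.matrix(sim) || nrow(sim) != n || ncol(sim) != n) {
    stop("similarity matrix dimensions do not match the library")
  }
  next_id <- n + 1L
  trees <- lapply(seq_len(n), function(i) {
    new_tree_node(i, fragment_ref = i, members = i)
  })
  # tree_sim[i, j]: single-linkage (max) similarity between active trees
  tree_sim <- sim
  active <- seq_len(n)

  merge_pair <- function(ia, ib) {
    a <- trees[[ia]]; b <- trees[[ib]]
    if (min(b$members) < min(a$members)) { tmp <- a; a <- b; b <- tmp }
    node <- new_tree_node(next_id, left = a, right = b,
                          members = sort(c(a$members, b$members)))
    next_id <<- next_id + 1L
    node
  }

  while (length(active) > 1L) {
    unpaired <- active
    merged_this_round <- list()
    while (length(unpaired) > 1L) {
      # most similar pair among trees untouched this round, tolerant compare
      sub <- tree_sim[unpaired, unpaired, drop = FALSE]
      diag(sub) <- -Inf
      smax <- max(sub)
      best <- NULL
      for (x in seq_along(unpaired)) {
        for (y in seq_along(unpaired)) {
          if (y <= x) next
          if (sub[x, y] >= smax - 1e-12) {
            ka <- trees[[unpaired[x]]]; kb <- trees[[unpaired[y]]]
            key <- c(min(ka$members, kb$members),
                     max(min(ka$members), min(kb$members)))
            if (is.null(best) || key[1] < best$key[1] ||
                (key[1] == best$key[1] && key[2] < best$key[2])) {
              best <- list(x = unpaired[x], y = unpaired[y], key = key)
            }
          }
        }
      }
      node <- merge_pair(best$x, best$y)
      trees[[best$x]] <- node
      # merged row = elementwise max (single linkage); slot y retired
      tree_sim[best$x, ] <- pmax(tree_sim[best$x, ], tree_sim[best$y, ])
      tree_sim[, best$x] <- tree_sim[best$x, ]
      unpaired <- setdiff(unpaired, c(best$x, best$y))
      active <- setdiff(active, best$y)
      merged_this_round <- c(merged_this_round, best$x)
    }
    # an odd leftover tree is promoted unchanged
  }
  root <- trees[[active]]
  codes <- character(n)
  walk <- function(node, prefix) {
    if (!is.null(node$fragment_ref)) {
      codes[node$fragment_ref] <<- prefix
      return(invisible())
    }
    walk(node$left, paste0(prefix, "1"))
    walk(node$right, paste0(prefix, "0"))
  }
  walk(root, "")
  structure(list(root = root, codes = codes, n_leaves = n),
            class = "fragrl_tree")
}

#' @export
print.fragrl_tree <- function(x, ...) {
  cat(sprintf("<fragment tree> %d leaves, max code length %d\n",
              x$n_leaves, max(nchar(x$codes))))
  invisible(x)
}

#' Binary code of a library fragment
#'
#' @param tree a `fragrl_tree`
#' @param frag_index library position (1-based)
#' @return the fragment's bit-string code ("" for a single-leaf tree)
#' @export
encode_fragment <- function(tree, frag_index) {
  stopifnot(inherits(tree, "fragrl_tree"))
  if (!(frag_index %in% seq_len(tree$n_leaves))) {
    stop("unknown fragment index: ", frag_index)
  }
  tree$codes[[frag_index]]
}

#' Decode a bit-string back to its library fragment
#'
#' @param tree a `fragrl_tree`
#' @param code character bit-string over {0,1}
#' @return the library index of the addressed leaf
#' @export
decode_code <- function(tree, code) {
  stopifnot(inherits(tree, "fragrl_tree"), is.character(code),
            length(code) == 1L)
  node <- tree$root
  for (bit in strsplit(code, "")[[1]]) {
    if (!is.null(node$fragment_ref)) stop("code walks off the tree: ", code)
    node <- if (bit == "1") node$left else if (bit == "0") node$right
    else stop("invalid code symbol: ", bit)
  }
  if (is.null(node$fragment_ref)) {
    stop("code stops at an internal node: ", code)
  }
  node$fragment_ref
}
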