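#' @name mcs
#' @title Maximum common substructure over heavy-atom graphs
#'
#' @description
#' Connected maximum-common-substructure search used by the TMCS fragment
#' similarity. Atoms match on (element, aromaticity); bonds match regardless
#' of order, so tautomer-like bond-order differences are ignored. Attachment
#' placeholders are excluded from the graphs before matching, and all counts
#' are heavy-atom counts.
#'
#' The search is a branch-and-bound over label-preserving, common-edge
#' connected extensions: a candidate atom pair can join the current mapping
#' only if it is linked to an already-mapped pair by a bond present in both
#' molecules, which restricts enumeration to connected common subgraphs. A
#' per-pair expansion budget bounds worst-case time; if it is ever exhausted
#' the best size found so far is returned as a lower bound (with a warning),
#' which on fragment-sized inputs does not occur at the default budget.
NULL

# Internal graph form: list(n, labels (character), adj (list of integer),
# amat (n x n logical)).
mcs_graph <- function(backend_graph) {
  if (is.null(backend_graph)) stop("invalid structure: no graph")
  atoms <- backend_graph$atoms
  n <- length(atoms)
  labels <- vapply(atoms, function(a) paste0(a[[1]], "_", a[[2]]), character(1))
  amat <- matrix(FALSE, n, n)
  adj <- rep(list(integer()), n)
  for (b in backend_graph$bonds) {
    i <- b[[1]]; j <- b[[2]]
    amat[i, j] <- TRUE; amat[j, i] <- TRUE
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  list(n = n, labels = labels, adj = adj, amat = amat)
}

graph_for_smiles <- function(smiles) {
  lapply(chem_graph(smiles), mcs_graph)
}

#' Connected MCS size between two heavy-atom graphs
#'
#' @param g1,g2 graphs from [graph_for_smiles()]
#' @param budget maximum number of search-tree expansions before the current
#'   best is returned as a lower bound
#' @return integer heavy-atom count of the maximum common connected
#'   substructure
#' @keywords internal
mcs_size <- function(g1, g2, budget = 2e6) {
  if (g1$n == 0L || g2$n == 0L) return(0L)
  if (g1$n > g2$n) { tmp <- g1; g1 <- g2; g2 <- tmp }
  env <- new.env(parent = emptyenv())
  env$best <- 0L
  env$nodes <- 0L
  env$capped <- FALSE

  lab2_count <- table(g2$labels)
  # quick infeasibility: labels of g1 with no counterpart can never map
  matchable <- g1$labels %in% names(lab2_count)
  ub_global <- sum(pmin(table(g1$labels[matchable]),
                        lab2_count[names(table(g1$labels[matchable]))]))
  if (ub_global == 0L) return(0L)

  n1 <- g1$n
  extend <- function(m1, m2, used1, used2, forbidden, start) {
    size <- length(m1)
    if (size > env$best) env$best <- size
    env$nodes <- env$nodes + 1L
    if (env$nodes > budget) { env$capped <- TRUE; return(invisible()) }
    # upper bound: current + label-multiset overlap of the unmapped remainder
    free1 <- which(!used1 & !forbidden)
    free1 <- free1[free1 > start]
    if (size + length(free1) <= env$best) return(invisible())
    free2 <- which(!used2)
    t1 <- table(g1$labels[free1]); t2 <- table(g2$labels[free2])
    common <- intersect(names(t1), names(t2))
    if (size + sum(pmin(t1[common], t2[common])) <= env$best) {
      return(invisible())
    }
    # candidate g1 atoms: common-edge adjacent to the mapped set
    cand1 <- integer()
    for (k in seq_along(m1)) {
      nb <- g1$adj[[m1[k]]]
      nb <- nb[!used1[nb] & !forbidden[nb] & nb > start]
      cand1 <- union(cand1, nb[vapply(nb, function(i) {
        any(g2$amat[m2[k], ] & !used2 & g2$labels == g1$labels[i] &
              seq_len(g2$n) %in% g2$adj[[m2[k]]])
      }, logical(1))])
    }
    if (length(cand1) == 0L) return(invisible())
    i <- min(cand1)
    # images of i: unmapped g2 atoms, label match, common-edge adjacency
    imgs <- integer()
    for (k in seq_along(m1)) {
      if (g1$amat[m1[k], i]) {
        nb2 <- g2$adj[[m2[k]]]
        imgs <- union(imgs, nb2[!used2[nb2] & g2$labels[nb2] == g1$labels[i]])
      }
    }
    for (j in sort(imgs)) {
      used1[i] <- TRUE; used2[j] <- TRUE
      extend(c(m1, i), c(m2, j), used1, used2, forbidden, start)
      used1[i] <- FALSE; used2[j] <- FALSE
      if (env$capped) return(invisible())
    }
    # branch where i is excluded from this subtree entirely
    forbidden[i] <- TRUE
    extend(m1, m2, used1, used2, forbidden, start)
  }

  for (s in seq_len(n1)) {
    if (n1 - s + 1L <= env$best) break
    js <- which(g2$labels == g1$labels[s])
    for (j in js) {
      used1 <- rep(FALSE, n1); used2 <- rep(FALSE, g2$n)
      used1[s] <- TRUE; used2[j] <- TRUE
      forbidden <- rep(FALSE, n1)
      extend(s, j, used1, used2, forbidden, s)
      if (env$capped) break
    }
    if (env$capped) break
  }
  if (env$capped) {
    warning("MCS search budget exhausted; returning lower bound",
            call. = FALSE)
  }
  as.integer(env$best)
}
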