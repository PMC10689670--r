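#' @name fragmentation
#' @title Fragment combination library
#'
#' @description
#' Molecules are partitioned into ring structures, linkers and side chains by
#' cleaving every acyclic single bond that extends from a ring atom; each
#' cleavage leaves a pair of numbered attachment points so the molecule can
#' be reassembled exactly. The union of fragments over a compound set forms
#' the virtual fragment combination library, and pairwise fragment
#' similarities are measured with the Tanimoto-MCS coefficient
#' `TMCS = mcs / (a1 + a2 - mcs)` where `mcs` is the heavy-atom count of the
#' maximum common substructure and `a1`, `a2` the fragments' heavy-atom
#' counts.
NULL

new_fragment <- function(smiles, atom_count, n_attach, frag_class) {
  structure(
    list(smiles = smiles, atom_count = as.integer(atom_count),
         n_attach = as.integer(n_attach), frag_class = frag_class,
         attachment_points = if (n_attach > 0) {
           data.frame(point = seq_len(n_attach), bond_order = 1L)
         } else {
           data.frame(point = integer(), bond_order = integer())
         }),
    class = "fragrl_fragment")
}

#' @export
print.fragrl_fragment <- function(x, ...) {
  cat(sprintf("<fragment> %s  [%s, %d heavy atoms, %d attachment point(s)]\n",
              x$smiles, x$frag_class, x$atom_count, x$n_attach))
  invisible(x)
}

fragment_from_record <- function(rec) {
  new_fragment(rec$smiles, rec$atom_count, rec$n_attach, rec$frag_class)
}

#' Cleave a molecule into ring, linker and side-chain fragments
#'
#' Every acyclic single bond with at least one ring-atom endpoint is cleaved
#' (so the biphenyl ring-ring bond is eligible); rings themselves are never
#' opened. Fragments are classified `ring` (contains a cycle), `linker`
#' (acyclic, >= 2 attachment points) or `side_chain` (acyclic, <= 1).
#' A molecule with no eligible bond is returned whole as a single fragment.
#'
#' @param smiles a single SMILES string
#' @return a list with elements `fragments` (list of fragment objects, in
#'   canonical-atom-rank order of each fragment's first parent atom),
#'   `map` (the decomposition map: `bonds`, a list of `c(frag_a, point_a,
#'   frag_b, point_b)` attachment pairings), and `canonical` (the canonical
#'   parent SMILES).
#' @export
#' @examples \dontrun{fragment_molecule("Cc1ccccc1")}
fragment_molecule <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  rec <- chem_fragment_raw(smiles)[[1]]
  if (!isTRUE(rec$ok)) stop("cannot fragment: ", rec$error)
  list(fragments = lapply(rec$fragments, fragment_from_record),
       map = list(bonds = lapply(rec$bonds, function(b) as.integer(unlist(b)))),
       canonical = rec$canonical)
}

#' Build the virtual fragment combination library
#'
#' Fragments every input molecule and collects the union of fragments,
#' deduplicated by canonical structure (attachment numbering normalized), in
#' first-occurrence order. Unparsable inputs are dropped with a warning.
#'
#' @param smiles character vector of molecule SMILES
#' @return a `fragrl_library`: list with `fragments` (list of fragments) and
#'   `index` (named integer, canonical structure -> position)
#' @export
build_fragment_library <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  recs <- chem_fragment_raw(smiles)
  ok <- vapply(recs, function(r) isTRUE(r$ok), logical(1))
  if (!any(ok)) stop("no input molecule could be parsed")
  if (any(!ok)) {
    warning(sum(!ok), " molecule(s) could not be parsed and were skipped")
  }
  fragments <- list()
  index <- integer()
  for (r in recs[ok]) {
    for (fr in r$fragments) {
      if (is.na(match(fr$smiles, names(index)))) {
        fragments[[length(fragments) + 1L]] <- fragment_from_record(fr)
        index[[fr$smiles]] <- length(fragments)
      }
    }
  }
  structure(list(fragments = fragments, index = index),
            class = "fragrl_library")
}

#' @export
print.fragrl_library <- function(x, ...) {
  cls <- table(vapply(x$fragments, `[[`, "", "frag_class"))
  cat(sprintf("<fragment library> %d fragments (%s)\n", length(x$fragments),
              paste(sprintf("%s: %d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' @export
length.fragrl_library <- function(x) length(x$fragments)

library_smiles <- function(lib) {
  vapply(lib$fragments, `[[`, character(1), "smiles")
}

#' Heavy-atom count of the maximum common substructure of two fragments
#'
#' Attachment placeholders are excluded from matching; atoms match on element
#' and aromaticity, bonds on existence only.
#'
#' @param f1,f2 fragment objects (from [fragment_molecule()] /
#'   [build_fragment_library()]) or SMILES strings
#' @return integer MCS heavy-atom count
#' @export
mcs_atom_count <- function(f1, f2) {
  s1 <- if (inherits(f1, "fragrl_fragment")) f1$smiles else f1
  s2 <- if (inherits(f2, "fragrl_fragment")) f2$smiles else f2
  gs <- graph_for_smiles(c(s1, s2))
  mcs_size(gs[[1]], gs[[2]])
}

#' Tanimoto-MCS similarity between two fragments
#'
#' `TMCS(M1, M2) = mcs(M1, M2) / (a(M1) + a(M2) - mcs(M1, M2))` with `a()`
#' the heavy-atom count. Symmetric, in `[0, 1]`, and 1 exactly when the two
#' fragments are isomorphic on heavy atoms.
#'
#' @inheritParams mcs_atom_count
#' @return similarity in `[0, 1]`
#' @export
#' @examples \dontrun{tmcs_similarity("c1ccccc1", "Cc1ccccc1")  # 6/7}
tmcs_similarity <- function(f1, f2) {
  s1 <- if (inherits(f1, "fragrl_fragment")) f1$smiles else f1
  s2 <- if (inherits(f2, "fragrl_fragment")) f2$smiles else f2
  gs <- graph_for_smiles(c(s1, s2))
  a1 <- gs[[1]]$n; a2 <- gs[[2]]$n
  stopifnot(a1 >= 1L, a2 >= 1L)
  m <- mcs_size(gs[[1]], gs[[2]])
  m / (a1 + a2 - m)
}

#' Pairwise TMCS similarity matrix of a fragment library
#'
#' @param lib a `fragrl_library`
#' @return symmetric numeric matrix with unit diagonal, one row/column per
#'   library fragment (dimnames = canonical structures)
#' @export
pairwise_similarity <- function(lib) {
  stopifnot(inherits(lib, "fragrl_library"), length(lib) >= 1L)
  smis <- library_smiles(lib)
  graphs <- graph_for_smiles(smis)
  n <- length(smis)
  m <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        sz <- mcs_size(graphs[[i]], graphs[[j]])
        m[i, j] <- m[j, i] <-
          sz / (graphs[[i]]$n + graphs[[j]]$n - sz)
      }
    }
  }
  dimnames(m) <- list(smis, smis)
  m
}
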