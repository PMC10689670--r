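#' @name assembly
#' @title Molecule states, fragment replacement and reassembly
#'
#' @description
#' A `molecule_state` is an ordered fragment decomposition of one molecule:
#' library indices, a scaffold mask (ring and linker fragments are scaffold,
#' side chains are not), the attachment-point pairing graph, and the
#' canonical SMILES of the assembled molecule. It is the state the policy
#' acts on; [replace_fragment()] is the action. All transformations are
#' pure: a state is never mutated in place.
NULL

new_molecule_state <- function(fragments, scaffold_mask, bond_graph, source,
                               valid = TRUE) {
  stopifnot(length(fragments) == length(scaffold_mask))
  structure(list(fragments = as.integer(fragments),
                 scaffold_mask = scaffold_mask,
                 bond_graph = bond_graph,
                 source = source, valid = valid),
            class = "fragrl_state")
}

#' @export
print.fragrl_state <- function(x, ...) {
  cat(sprintf("<molecule state> %s  [%d fragment(s), %d scaffold]\n",
              if (isTRUE(x$valid)) x$source else "<invalid>",
              length(x$fragments), sum(x$scaffold_mask)))
  invisible(x)
}

#' Decompose a molecule into a state over a fragment library
#'
#' @param smiles molecule SMILES
#' @param lib a `fragrl_library`; every fragment of the molecule must be
#'   present unless `extend = TRUE`
#' @param extend if TRUE (default FALSE) unknown fragments are appended to
#'   the library; the possibly-extended library is attached to the result as
#'   attribute "library"
#' @return a `fragrl_state`
#' @export
decompose <- function(smiles, lib, extend = FALSE) {
  dec <- fragment_molecule(smiles)
  smis <- vapply(dec$fragments, `[[`, character(1), "smiles")
  idx <- match(smis, names(lib$index))
  if (anyNA(idx)) {
    if (!extend) {
      stop("unknown fragment(s) not in library: ",
           paste(smis[is.na(idx)], collapse = ", "))
    }
    for (k in which(is.na(idx))) {
      lib$fragments[[length(lib$fragments) + 1L]] <- dec$fragments[[k]]
      lib$index[[smis[k]]] <- length(lib$fragments)
      idx[k] <- length(lib$fragments)
    }
  }
  classes <- vapply(dec$fragments, `[[`, character(1), "frag_class")
  st <- new_molecule_state(
    fragments = unname(lib$index[smis]),
    scaffold_mask = classes %in% c("ring", "linker"),
    bond_graph = dec$map$bonds,
    source = dec$canonical)
  attr(st, "library") <- lib
  st
}

bonds_at_position <- function(state, position) {
  hits <- list()
  for (k in seq_along(state$bond_graph)) {
    b <- state$bond_graph[[k]]
    if (b[1] == position) hits[[length(hits) + 1L]] <- c(k, b[2])
    if (b[3] == position) hits[[length(hits) + 1L]] <- c(k, b[4])
  }
  hits
}

#' Replace one fragment of a state
#'
#' The outgoing fragment's bonded attachment points, taken in ascending
#' order, are rewired to the incoming fragment's points `1..k` in ascending
#' order; surplus incoming points are left open (capped with hydrogen at
#' assembly). The source SMILES is recomputed; if reassembly fails the
#' returned state is flagged invalid (`valid = FALSE`, `source = NA`).
#'
#' @param state a `fragrl_state`
#' @param position fragment position to replace (1-based)
#' @param new_frag library index of the replacement fragment
#' @param lib the `fragrl_library` the state refers to
#' @return a new `fragrl_state`; the input is not modified
#' @export
replace_fragment <- function(state, position, new_frag, lib) {
  stopifnot(inherits(state, "fragrl_state"),
            position >= 1L, position <= length(state$fragments),
            new_frag >= 1L, new_frag <= length(lib))
  incoming <- lib$fragments[[new_frag]]
  at <- bonds_at_position(state, position)
  if (incoming$n_attach < length(at)) {
    stop("incompatible fragment: ", incoming$smiles, " has ",
         incoming$n_attach, " attachment point(s), position ", position,
         " needs ", length(at))
  }
  bond_graph <- state$bond_graph
  if (length(at) > 0L) {
    ord <- order(vapply(at, `[`, numeric(1), 2))
    for (r in seq_along(ord)) {
      k <- at[[ord[r]]][1]
      b <- bond_graph[[k]]
      if (b[1] == position && b[2] == at[[ord[r]]][2]) b[2] <- r else b[4] <- r
      bond_graph[[k]] <- b
    }
  }
  fragments <- state$fragments
  fragments[position] <- new_frag
  scaffold_mask <- state$scaffold_mask
  scaffold_mask[position] <- incoming$frag_class %in% c("ring", "linker")
  st <- new_molecule_state(fragments, scaffold_mask, bond_graph,
                           source = NA_character_, valid = FALSE)
  src <- try_assemble(st, lib)
  if (!is.na(src)) { st$source <- src; st$valid <- TRUE }
  st
}

try_assemble <- function(state, lib) {
  job <- list(frags = library_smiles(lib)[state$fragments],
              bonds = state$bond_graph)
  res <- chem_assemble_raw(list(job))[[1]]
  if (isTRUE(res$ok)) res$smiles else NA_character_
}

#' Assemble a state back into a molecule
#'
#' Bonds every paired attachment point, caps open points with hydrogen and
#' canonicalizes. A valence or sanitization failure raises an
#' invalid-molecule error (downstream callers catch it and count the
#' molecule invalid).
#'
#' @param state a `fragrl_state`
#' @param lib the `fragrl_library` the state refers to
#' @return canonical SMILES string
#' @export
assemble <- function(state, lib) {
  src <- try_assemble(state, lib)
  if (is.na(src)) stop("invalid molecule: assembly failed sanitization")
  src
}

#' Chemical validity of a structure string
#'
#' @param smiles character vector
#' @return logical: TRUE where the string parses and sanitizes (valence,
#'   aromaticity)
#' @export
#' @examples \dontrun{check_validity(c("c1ccccc1", "C1CC"))}
check_validity <- function(smiles) {
  chem_is_valid(smiles)
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Rings plus connecting linkers, side chains pruned, canonicalized. Acyclic
#' molecules have an empty scaffold ("").
#'
#' @param smiles character vector of valid molecules
#' @return character vector of scaffold SMILES
#' @export
bemis_murcko_scaffold <- function(smiles) {
  res <- chem_scaffold_raw(smiles)
  bad <- vapply(res, is.null, logical(1))
  if (any(bad)) stop("invalid molecule: ", paste(smiles[bad], collapse = ", "))
  vapply(res, identity, character(1))
}
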