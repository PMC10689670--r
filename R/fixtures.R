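#' @name fixtures
#' @title Seeded synthetic molecule fixtures
#'
#' @description
#' A deterministic generator of drug-like test molecules composed from a
#' built-in catalog of ring cores, linkers and side chains, so every module
#' is testable without external datasets. The catalog is chosen so that
#' molecular weight, logP and TPSA straddle the default property-gate
#' ranges (small single-ring molecules fall below MW 200; naphthalene/
#' quinoline two-core assemblies with polar side chains land inside or
#' above), and a nitro side chain exercises the toxicophore screen. What it
#' does not emulate: realistic scaffold frequency distributions,
#' stereochemistry, or charged/isotopic species.
NULL

fixture_catalog <- function() {
  # every part is "cleavage-atomic": rings carry no exocyclic single bonds
  # except the attachment dummies, linkers/side chains contain no ring atom,
  # so fragmenting a generated molecule recovers exactly these parts
  list(
    cores = list(
      list(smiles = "[*:1]c1ccccc1", n = 1L),
      list(smiles = "[*:1]c1ccc([*:2])cc1", n = 2L),
      list(smiles = "[*:1]c1cccc([*:2])c1", n = 2L),
      list(smiles = "[*:1]c1ccccc1[*:2]", n = 2L),
      list(smiles = "[*:1]c1ccncc1", n = 1L),
      list(smiles = "[*:1]c1ccc([*:2])nc1", n = 2L),
      list(smiles = "[*:1]c1ccncn1", n = 1L),
      list(smiles = "[*:1]c1cnccn1", n = 1L),
      list(smiles = "[*:1]c1cccs1", n = 1L),
      list(smiles = "[*:1]c1ccco1", n = 1L),
      list(smiles = "[*:1]c1cc[nH]c1", n = 1L),
      list(smiles = "[*:1]C1CC1", n = 1L),
      list(smiles = "[*:1]C1CCCC1", n = 1L),
      list(smiles = "[*:1]C1CCCCC1", n = 1L),
      list(smiles = "[*:1]C1CCC([*:2])CC1", n = 2L),
      list(smiles = "[*:1]C1CCCO1", n = 1L),
      list(smiles = "[*:1]C1CCNCC1", n = 1L),
      list(smiles = "[*:1]N1CCCCC1", n = 1L),
      list(smiles = "[*:1]N1CCOCC1", n = 1L),
      list(smiles = "[*:1]N1CCN([*:2])CC1", n = 2L),
      list(smiles = "[*:1]c1ccc2ccccc2c1", n = 1L),
      list(smiles = "[*:1]c1ccc2cc([*:2])ccc2c1", n = 2L),
      list(smiles = "[*:1]c1ccc2ncccc2c1", n = 1L)),
    linkers = c("[*:1]C[*:2]", "[*:1]CC[*:2]", "[*:1]CCC[*:2]",
                "[*:1]O[*:2]", "[*:1]OC[*:2]", "[*:1]COC[*:2]",
                "[*:1]N[*:2]", "[*:1]CNC[*:2]",
                "[*:1]C(=O)[*:2]", "[*:1]C(=O)N[*:2]", "[*:1]C(=O)O[*:2]",
                "[*:1]NC(=O)C[*:2]", "[*:1]S(=O)(=O)N[*:2]",
                "[*:1]C=C[*:2]", "[*:1]C#C[*:2]"),
    side_chains = c("C[*:1]", "CC[*:1]", "CCC[*:1]", "CCCC[*:1]",
                    "CC(C)[*:1]", "CC(C)(C)[*:1]",
                    "O[*:1]", "CO[*:1]", "OCC[*:1]", "N[*:1]", "CN[*:1]",
                    "CN(C)[*:1]", "Cl[*:1]", "F[*:1]", "Br[*:1]",
                    "FC(F)[*:1]", "FC(F)(F)[*:1]", "N#C[*:1]", "CS[*:1]",
                    "O=C(O)[*:1]", "NC(=O)[*:1]", "CC(=O)[*:1]",
                    "COC(=O)[*:1]", "CS(=O)(=O)[*:1]", "O=[N+]([O-])[*:1]",
                    "CN(C)CC[*:1]", "CNC(=O)[*:1]", "OC(=O)C[*:1]"))
}

#' Generate a deterministic synthetic molecule set
#'
#' @param n number of molecules, >= 1
#' @param seed integer seed
#' @param complexity "small" (one ring core plus side chains) or "medium"
#'   (two cores joined by a linker, side chains on remaining attachment
#'   points)
#' @return a `fragrl_fixtures` list: `molecules` (canonical SMILES),
#'   `n_parts` (intended fragment count per molecule), `seed`, `complexity`
#' @export
#' @examples \dontrun{generate_fixtures(10, seed = 1)}
generate_fixtures <- function(n, seed = 1L,
                              complexity = c("medium", "small")) {
  stopifnot(n >= 1L)
  complexity <- match.arg(complexity)
  cat <- fixture_catalog()
  rng <- rng_stream(seed)$derive(11)
  jobs <- vector("list", n)
  n_parts <- integer(n)
  for (i in seq_len(n)) {
    frags <- character()
    bonds <- list()
    open <- list()  # (position, point) pairs awaiting a side chain
    add_part <- function(smiles, n_attach) {
      frags[[length(frags) + 1L]] <<- smiles
      pos <- length(frags)
      for (p in seq_len(n_attach)) open[[length(open) + 1L]] <<- c(pos, p)
      pos
    }
    core1 <- cat$cores[[rng$sample_int(length(cat$cores))]]
    add_part(core1$smiles, core1$n)
    if (complexity == "medium") {
      core2 <- cat$cores[[rng$sample_int(length(cat$cores))]]
      linker <- cat$linkers[[rng$sample_int(length(cat$linkers))]]
      # core1 point 1 - linker point 1; linker point 2 - core2 point 1
      lp <- add_part(linker, 0L)
      cp2 <- add_part(core2$smiles, core2$n)
      bonds[[length(bonds) + 1L]] <- c(1L, 1L, lp, 1L)
      bonds[[length(bonds) + 1L]] <- c(lp, 2L, cp2, 1L)
      open <- Filter(function(x) !(x[1] == 1L && x[2] == 1L) &&
                       !(x[1] == cp2 && x[2] == 1L), open)
    }
    # fill every remaining attachment point with a side chain; guarantee at
    # least two fragments overall
    if (length(open) == 0L) open <- list()  # single-attachment cores covered
    for (op in open) {
      sc <- cat$side_chains[[rng$sample_int(length(cat$side_chains))]]
      sp <- add_part(sc, 0L)
      bonds[[length(bonds) + 1L]] <- c(op[1], op[2], sp, 1L)
    }
    jobs[[i]] <- list(frags = frags, bonds = bonds)
    n_parts[i] <- length(frags)
  }
  res <- chem_assemble_raw(jobs)
  ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
  if (!all(ok)) {
    stop("fixture assembly failed for ", sum(!ok), " molecule(s): ",
         res[[which(!ok)[1]]]$error)
  }
  structure(list(molecules = vapply(res, `[[`, character(1), "smiles"),
                 n_parts = n_parts, seed = as.integer(seed),
                 complexity = complexity),
            class = "fragrl_fixtures")
}
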