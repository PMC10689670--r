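#' @name cli_io
#' @title File I/O and run configuration
#'
#' @description
#' Readers and writers for the package's exchange formats: SMILES lists
#' (`.smi`, one molecule per line, optional tab-separated name; blank and
#' `#` lines skipped), CSV with a configurable SMILES column, JSON for
#' fragment libraries, trees, similarity matrices and metric records, and a
#' JSON run configuration with materialized defaults and unknown-key
#' rejection.
NULL

#' Read molecules from a .smi or CSV file
#'
#' Order-preserving; blank lines and `#` comments are skipped; lines that
#' fail to parse are dropped with a warning naming their line numbers.
#'
#' @param path input file
#' @param format "auto" (by extension), "smi" or "csv"
#' @param smiles_col CSV column holding SMILES
#' @return character vector of SMILES (not canonicalized)
#' @export
read_molecules <- function(path, format = c("auto", "smi", "csv"),
                           smiles_col = "smiles") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "smi"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!smiles_col %in% names(df)) {
      stop("CSV has no column named '", smiles_col, "'")
    }
    smis <- as.character(df[[smiles_col]])
    lineno <- seq_along(smis) + 1L
  } else {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
    smis <- vapply(strsplit(trimws(lines[keep]), "[ \t]+"), `[[`, "", 1L)
    lineno <- which(keep)
  }
  ok <- chem_is_valid(smis)
  if (!any(ok)) {
    stop("no parseable molecule in ", path, " (bad lines: ",
         paste(lineno[!ok], collapse = ", "), ")")
  }
  if (any(!ok)) {
    warning(sum(!ok), " unparseable line(s) skipped: line ",
            paste(lineno[!ok], collapse = ", "))
  }
  smis[ok]
}

#' Write molecules to a .smi file
#' @param smiles character vector
#' @param path output path
#' @return invisibly, `path`
#' @export
write_molecules <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}

default_config <- function() {
  list(
    seed = 1L,
    model = list(heads = 4L, blocks = 2L, d_f = 64L, d_p = 16L,
                 head_hidden = 64L, max_positions = 32L),
    reward = list(
      ranges = default_property_ranges(),
      weights = default_reward_weights(),
      toxicophore_file = NULL,
      use_property_optimization = TRUE),
    rl = list(gamma = 0.99, lr_actor = 3e-4, lr_critic = 3e-4,
              entropy_coef = 0.01, time = 1L, epochs = 100L,
              batch_size = 32L, time_schedule = "fixed",
              plateau_window = 50L, plateau_tol = 0.005),
    docking = list(enabled = FALSE, engine = "mock", workers = 1L,
                   retry_limit = 1L, aggregate = "best"))
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults)) {
      stop("unknown configuration key: ", key)
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]])) stop("configuration key ", key,
                                     " must be a mapping")
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], key)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a JSON run configuration
#'
#' Merges the file over the package defaults (the default property ranges
#' are the shipped MW/logP/TPSA/toxicophore targets), rejects unknown keys
#' by name, and optionally echoes the fully resolved configuration into a
#' run directory.
#'
#' @param path JSON file; NULL for pure defaults
#' @param run_dir if non-NULL, the resolved config is written to
#'   `run_dir/config.json`
#' @return nested configuration list
#' @export
load_config <- function(path = NULL, run_dir = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
    if (length(user) > 0L) cfg <- merge_config(cfg, user)
  }
  cfg$reward$ranges <- lapply(cfg$reward$ranges, as.numeric)
  if (!is.null(run_dir)) {
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(cfg, file.path(run_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         digits = NA)
  }
  cfg
}

#' Convert a configuration to a training config
#' @param cfg list from [load_config()]
#' @param activity_fn optional activity oracle
#' @return a `fragrl_train_config`
#' @export
config_to_train <- function(cfg, activity_fn = NULL) {
  screen_file <- cfg$reward$toxicophore_file
  train_config(
    gamma = cfg$rl$gamma, lr_actor = cfg$rl$lr_actor,
    lr_critic = cfg$rl$lr_critic, entropy_coef = cfg$rl$entropy_coef,
    time = cfg$rl$time, epochs = cfg$rl$epochs,
    batch_size = cfg$rl$batch_size, seed = cfg$seed,
    ranges = cfg$reward$ranges, weights = cfg$reward$weights,
    use_property_optimization = cfg$reward$use_property_optimization,
    activity_fn = activity_fn, time_schedule = cfg$rl$time_schedule,
    plateau_window = cfg$rl$plateau_window,
    plateau_tol = cfg$rl$plateau_tol)
}

#' @rdname config_to_train
#' @export
config_to_dims <- function(cfg) {
  policy_dims(H = cfg$model$heads, d_f = cfg$model$d_f, d_p = cfg$model$d_p,
              L = cfg$model$blocks, head_hidden = cfg$model$head_hidden,
              max_positions = cfg$model$max_positions)
}

# ---- library / tree / matrix serialization --------------------------------

#' Serialize a fragment library to JSON
#' @param lib a `fragrl_library`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_library <- function(lib, path) {
  recs <- lapply(lib$fragments, function(f) {
    list(structure = f$smiles, frag_class = f$frag_class,
         atom_count = f$atom_count, n_attach = f$n_attach)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fragment library from JSON
#' @param path JSON file from [write_library()]
#' @return a `fragrl_library`
#' @export
read_library <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fragments <- lapply(recs, function(r) {
    new_fragment(r$structure, r$atom_count, r$n_attach, r$frag_class)
  })
  index <- seq_along(fragments)
  names(index) <- vapply(fragments, `[[`, character(1), "smiles")
  structure(list(fragments = fragments, index = index),
            class = "fragrl_library")
}

#' Serialize a fragment tree to JSON
#' @param tree a `fragrl_tree`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_tree <- function(tree, path) {
  strip <- function(node) {
    if (!is.null(node$fragment_ref)) {
      return(list(node_id = node$node_id, fragment_ref = node$fragment_ref))
    }
    list(node_id = node$node_id, left = strip(node$left),
         right = strip(node$right))
  }
  jsonlite::write_json(list(root = strip(tree$root),
                            codes = as.list(tree$codes),
                            n_leaves = tree$n_leaves),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fragment tree from JSON
#' @param path JSON file from [write_tree()]
#' @return a `fragrl_tree`
#' @export
read_tree <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rebuild <- function(node) {
    if (!is.null(node$fragment_ref)) {
      return(new_tree_node(node$node_id,
                           fragment_ref = as.integer(node$fragment_ref),
                           members = as.integer(node$fragment_ref)))
    }
    l <- rebuild(node$left); r <- rebuild(node$right)
    new_tree_node(node$node_id, left = l, right = r,
                  members = sort(c(l$members, r$members)))
  }
  structure(list(root = rebuild(obj$root),
                 codes = vapply(obj$codes, identity, character(1)),
                 n_leaves = as.integer(obj$n_leaves)),
            class = "fragrl_tree")
}

#' Write / read a similarity matrix as CSV
#' @param sim numeric matrix
#' @param path CSV path
#' @return invisibly `path`; `read_similarity` returns the matrix
#' @export
write_similarity <- function(sim, path) {
  utils::write.csv(sim, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}
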