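#' @name chem-backend
#' @title RDKit chemistry backend
#'
#' @description
#' fragrl delegates standard cheminformatics primitives (SMILES parsing and
#' canonicalization, sanitization, bond cleavage and reassembly, descriptors,
#' SMARTS matching, Murcko scaffolds, Morgan fingerprints, SA and QED) to
#' RDKit through a small Python helper shipped in `inst/python/`. A persistent
#' JSON-over-socket server is started lazily on first use; if a socket cannot
#' be established the package transparently falls back to one-shot subprocess
#' calls. All wrappers are vectorized and memoised, so repeated queries for
#' the same structure never touch Python twice.
#'
#' The Python interpreter is located via `getOption("fragrl.python")`, the
#' `FRAGRL_PYTHON` environment variable, or `Sys.which("python")`, in that
#' order. It must have RDKit importable.
NULL

.fragrl <- new.env(parent = emptyenv())

backend_python <- function() {
  p <- getOption("fragrl.python", "")
  if (!nzchar(p)) p <- Sys.getenv("FRAGRL_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no python interpreter found for the chemistry backend")
  p
}

backend_script <- function() {
  s <- system.file("python", "chem_backend.py", package = "fragrl")
  if (!nzchar(s)) stop("chem_backend.py not found in installed package")
  s
}

#' Start the chemistry backend server
#'
#' Called automatically on first use. Starts the RDKit helper process and
#' connects to it over a localhost socket; on any failure the backend drops
#' to one-shot subprocess mode.
#' @return invisibly, the backend mode ("server" or "batch")
#' @keywords internal
chem_backend_start <- function() {
  if (!is.null(.fragrl$mode)) return(invisible(.fragrl$mode))
  .fragrl$cache <- new.env(hash = TRUE, parent = emptyenv())
  base_port <- 20000L + (Sys.getpid() * 7L) %% 20000L
  for (attempt in 1:4) {
    port <- base_port + (attempt - 1L) * 17L
    log <- file.path(tempdir(), sprintf("fragrl-backend-%d.log", port))
    system2(backend_python(), c(backend_script(), "server", port),
            wait = FALSE, stdout = log, stderr = log)
    con <- NULL
    for (i in 1:150) {  # rdkit import can take several seconds
      Sys.sleep(0.1)
      ok <- file.exists(log) &&
        any(grepl("^READY", tryCatch(readLines(log, warn = FALSE),
                                     error = function(e) character())))
      if (!ok) next
      con <- tryCatch(
        suppressWarnings(socketConnection("127.0.0.1", port, blocking = TRUE,
                                          open = "r+", timeout = 600)),
        error = function(e) NULL)
      break
    }
    if (!is.null(con)) {
      .fragrl$con <- con
      .fragrl$mode <- "server"
      pong <- tryCatch(chem_call("ping", list()), error = function(e) NULL)
      if (identical(pong, "pong")) return(invisible("server"))
      try(close(con), silent = TRUE)
      .fragrl$con <- NULL
      .fragrl$mode <- NULL
    }
  }
  .fragrl$mode <- "batch"
  invisible("batch")
}

#' Stop the chemistry backend server
#' @return invisibly TRUE
#' @keywords internal
chem_backend_stop <- function() {
  if (!is.null(.fragrl$con)) try(close(.fragrl$con), silent = TRUE)
  .fragrl$con <- NULL
  .fragrl$mode <- NULL
  invisible(TRUE)
}

chem_call_batch <- function(op, payload) {
  req <- jsonlite::toJSON(list(list(op = op, payload = payload)),
                          auto_unbox = TRUE, digits = NA, null = "null")
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  writeLines(req, fin)
  status <- system2(backend_python(), c(backend_script(), "batch"),
                    stdin = fin, stdout = fout, stderr = FALSE)
  if (!identical(status, 0L)) stop("chemistry backend subprocess failed")
  jsonlite::fromJSON(readLines(fout, warn = FALSE), simplifyVector = FALSE)[[1]]
}

#' Low-level backend call
#' @param op backend operation name
#' @param payload named list, JSON-serializable
#' @return the backend's result (lists, not simplified)
#' @keywords internal
chem_call <- function(op, payload) {
  chem_backend_start()
  resp <- NULL
  if (identical(.fragrl$mode, "server")) {
    resp <- tryCatch({
      line <- jsonlite::toJSON(list(op = op, payload = payload),
                               auto_unbox = TRUE, digits = NA, null = "null")
      writeLines(line, .fragrl$con)
      flush(.fragrl$con)
      ans <- readLines(.fragrl$con, n = 1L)
      if (length(ans) == 0L) stop("backend connection closed")
      jsonlite::fromJSON(ans, simplifyVector = FALSE)
    }, error = function(e) NULL)
    if (is.null(resp)) {  # server died: drop to subprocess mode for good
      chem_backend_stop()
      .fragrl$mode <- "batch"
    }
  }
  if (is.null(resp)) resp <- chem_call_batch(op, payload)
  if (!isTRUE(resp$ok)) stop("chemistry backend error: ", resp$error)
  resp$result
}

# Memoised positional op over SMILES: one backend round trip for cache misses.
chem_vec_op <- function(op, smiles, payload_extra = NULL, key_extra = "") {
  stopifnot(is.character(smiles))
  keys <- paste0(op, "\r", key_extra, "\r", smiles)
  hit <- vapply(keys, exists, logical(1), envir = .fragrl$cache %||% {
    chem_backend_start(); .fragrl$cache
  }, USE.NAMES = FALSE)
  if (any(!hit)) {
    miss <- unique(smiles[!hit])
    payload <- c(list(smiles = as.list(miss)), payload_extra)
    res <- chem_call(op, payload)
    mkeys <- paste0(op, "\r", key_extra, "\r", miss)
    for (i in seq_along(miss)) assign(mkeys[i], res[[i]], envir = .fragrl$cache)
  }
  lapply(keys, get, envir = .fragrl$cache)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonicalize SMILES
#' @param smiles character vector
#' @return character vector of canonical SMILES, `NA` where parsing fails
#' @export
#' @examples \dontrun{chem_canonical("C1=CC=CC=C1")}
chem_canonical <- function(smiles) {
  res <- chem_vec_op("canonical", smiles)
  vapply(res, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

chem_is_valid <- function(smiles) {
  vapply(chem_vec_op("validity", smiles), isTRUE, logical(1))
}

chem_fragment_raw <- function(smiles) chem_vec_op("fragment", smiles)

chem_graph <- function(smiles) chem_vec_op("graph", smiles)

chem_descriptors <- function(smiles) chem_vec_op("descriptors", smiles)

chem_smarts <- function(smiles, patterns) {
  key <- paste(patterns, collapse = "|")
  chem_vec_op("smarts", smiles, list(patterns = as.list(patterns)), key)
}

chem_scaffold_raw <- function(smiles) chem_vec_op("scaffold", smiles)

chem_fingerprint <- function(smiles, nbits = 2048L, radius = 2L) {
  res <- chem_vec_op("fingerprint", smiles,
                     list(nbits = nbits, radius = radius),
                     paste(nbits, radius))
  lapply(res, function(x) if (is.null(x)) NULL else as.integer(unlist(x)))
}

chem_sa <- function(smiles) {
  vapply(chem_vec_op("sa", smiles),
         function(x) if (is.null(x)) NA_real_ else as.numeric(x), numeric(1))
}

chem_qed <- function(smiles) {
  vapply(chem_vec_op("qed", smiles),
         function(x) if (is.null(x)) NA_real_ else as.numeric(x), numeric(1))
}

# Assemble jobs: list of list(frags = character, bonds = list of c(fa,pa,fb,pb)).
chem_assemble_raw <- function(jobs) {
  chem_backend_start()
  keys <- vapply(jobs, function(j) {
    paste0("assemble\r", paste(j$frags, collapse = "\a"), "\r",
           paste(unlist(j$bonds), collapse = ","))
  }, character(1))
  hit <- vapply(keys, exists, logical(1), envir = .fragrl$cache,
                USE.NAMES = FALSE)
  if (any(!hit)) {
    midx <- which(!hit & !duplicated(keys))
    payload_jobs <- lapply(jobs[midx], function(j) {
      list(frags = as.list(j$frags),
           bonds = lapply(j$bonds, as.integer))
    })
    res <- chem_call("assemble", list(jobs = payload_jobs))
    for (i in seq_along(midx)) {
      assign(keys[midx[i]], res[[i]], envir = .fragrl$cache)
    }
  }
  lapply(keys, get, envir = .fragrl$cache)
}
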