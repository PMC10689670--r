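#' @name docking_farm
#' @title Master/worker docking-farm executor
#'
#' @description
#' A deterministic work-queue model of the master/worker docking scheduler:
#' a target-management role supplies target structures and pocket
#' definitions, ligand-management roles supply ligand batches, and worker
#' slots execute docking tasks, with bounded retries on engine failure.
#' Results are invariant to the worker count and to task arrival order when
#' the engine is deterministic — the scheduling-independence contract that
#' makes desk-scale testing meaningful. Real MPI deployment is out of
#' scope; an external docking binary can be plugged in through
#' [command_engine()], while [mock_engine()] provides a pure seeded
#' stand-in.
NULL

#' Plan docking tasks
#'
#' Cartesian product of targets and ligands (batched by ligand set), in
#' deterministic order; tasks are keyed by position, so duplicate ligand
#' references still yield one task each.
#'
#' @param targets character vector of opaque target references (e.g. PDB
#'   paths)
#' @param ligand_sets list of character vectors of ligand references
#'   (SMILES or file paths)
#' @param pockets optional list of docking-box parameters, one per target
#'   (`list(center = c(x, y, z), extents = c(dx, dy, dz))`), passed through
#'   to the engine
#' @return data.frame of `DockingTask`s: task_id, target_ref, ligand_ref,
#'   ligand_set
#' @export
plan_tasks <- function(targets, ligand_sets, pockets = NULL) {
  stopifnot(length(targets) > 0L, length(ligand_sets) > 0L)
  if (is.character(ligand_sets)) ligand_sets <- list(ligand_sets)
  stopifnot(all(lengths(ligand_sets) > 0L))
  rows <- list()
  id <- 0L
  for (set_i in seq_along(ligand_sets)) {
    for (t_i in seq_along(targets)) {
      for (lig in ligand_sets[[set_i]]) {
        id <- id + 1L
        rows[[id]] <- data.frame(task_id = id, target_ref = targets[t_i],
                                 ligand_ref = lig, ligand_set = set_i,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  tasks <- do.call(rbind, rows)
  attr(tasks, "pockets") <- pockets
  tasks
}

# stable FNV-1a-style string hash in double arithmetic (exact below 2^53)
stable_hash <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- (bitwXor(as.integer(h %% 2^31), b) + (h %/% 2^31) * 7) * 16777619
    h <- h %% 2^31
  }
  h
}

#' Seeded mock docking engine
#'
#' A pure function of (target_ref, ligand_ref, seed): scores are a stable
#' hash mapped into `[-12, -2]`. With `heavy_bias > 0` the score is
#' additionally lowered (improved) in proportion to the ligand's heavy-atom
#' count (capped at 30 atoms), which makes activity learnable from mock
#' docking runs.
#'
#' @param seed integer seed
#' @param heavy_bias per-heavy-atom score bias (requires ligand_ref to be
#'   SMILES)
#' @return an engine: `function(task) score`, with attributes
#'   `deterministic = TRUE` and `timeout`
#' @export
mock_engine <- function(seed = 1L, heavy_bias = 0) {
  fn <- function(task) {
    h <- stable_hash(paste(task$target_ref, task$ligand_ref, seed,
                           sep = "\r"))
    score <- -2 - 10 * (h / 2^31)
    if (heavy_bias > 0) {
      d <- chem_descriptors(task$ligand_ref)[[1]]
      if (isTRUE(d$valid)) {
        score <- score - heavy_bias * min(d$heavy, 30L)
      }
    }
    score
  }
  structure(fn, deterministic = TRUE, timeout = Inf,
            class = c("fragrl_engine", "function"))
}

#' External-command docking engine adapter
#'
#' Wraps a shell command template; `{target}`, `{ligand}` and `{pocket}`
#' placeholders are substituted per task and the score is parsed from the
#' command's output with a regular expression. No binary is bundled or
#' validated; this is the integration point for tools such as Ledock.
#'
#' @param template command template string
#' @param score_regex regex whose first capture group is the score
#' @param timeout seconds per task
#' @return an engine function
#' @export
command_engine <- function(template, score_regex = "([-0-9.]+)",
                           timeout = 300) {
  fn <- function(task) {
    cmd <- gsub("\\{target\\}", task$target_ref,
                gsub("\\{ligand\\}", task$ligand_ref, template))
    out <- suppressWarnings(system(cmd, intern = TRUE, timeout = timeout))
    m <- regmatches(out, regexec(score_regex, out))
    hit <- which(vapply(m, length, integer(1)) >= 2L)
    if (length(hit) == 0L) stop("no score in engine output")
    as.numeric(m[[hit[1]]][2])
  }
  structure(fn, deterministic = FALSE, timeout = timeout,
            class = c("fragrl_engine", "function"))
}

#' Run the docking farm
#'
#' Executes every task at most `retry_limit` times on a simulated pool of
#' `workers` worker slots (round-robin dispatch; failed tasks are
#' re-enqueued). Every submitted task yields exactly one result row; a task
#' failing beyond the retry limit is reported with status "failed" and the
#' farm continues.
#'
#' @param tasks data.frame from [plan_tasks()] (may have zero rows)
#' @param engine an engine function (see [mock_engine()])
#' @param workers number of worker slots, >= 1
#' @param retry_limit maximum attempts per task
#' @return data.frame ordered by task_id: task_id, target_ref, ligand_ref,
#'   score, status, attempts
#' @export
run_farm <- function(tasks, engine, workers = 1L, retry_limit = 1L) {
  stopifnot(workers >= 1L, retry_limit >= 1L)
  n <- nrow(tasks)
  results <- data.frame(task_id = integer(), target_ref = character(),
                        ligand_ref = character(), score = numeric(),
                        status = character(), attempts = integer(),
                        stringsAsFactors = FALSE)
  if (n == 0L) return(results)
  queue <- tasks$task_id
  attempts <- setNames(integer(n), tasks$task_id)
  scores <- setNames(rep(NA_real_, n), tasks$task_id)
  status <- setNames(rep("pending", n), tasks$task_id)
  while (length(queue) > 0L) {
    # dispatch one round: up to `workers` tasks taken from the queue head
    round_ids <- queue[seq_len(min(workers, length(queue)))]
    queue <- queue[-seq_len(length(round_ids))]
    for (id in round_ids) {
      row <- tasks[tasks$task_id == id, , drop = FALSE]
      attempts[[as.character(id)]] <- attempts[[as.character(id)]] + 1L
      res <- tryCatch(engine(as.list(row[1, ])), error = function(e) e)
      if (inherits(res, "error") || !is.finite(res)) {
        if (attempts[[as.character(id)]] < retry_limit) {
          queue <- c(queue, id)  # re-enqueue for another attempt
        } else {
          status[[as.character(id)]] <- "failed"
        }
      } else {
        scores[[as.character(id)]] <- res
        status[[as.character(id)]] <- "ok"
      }
    }
  }
  out <- data.frame(task_id = tasks$task_id, target_ref = tasks$target_ref,
                    ligand_ref = tasks$ligand_ref,
                    score = unname(scores[as.character(tasks$task_id)]),
                    status = unname(status[as.character(tasks$task_id)]),
                    attempts = unname(attempts[as.character(tasks$task_id)]),
                    stringsAsFactors = FALSE)
  out[order(out$task_id), , drop = FALSE]
}

#' Aggregate per-ligand docking scores across targets
#'
#' The reward layer consumes one score per ligand; scores across target
#' conformations are aggregated with `best` (minimum, default) or `mean`.
#'
#' @param results data.frame from [run_farm()]
#' @param aggregate "best" or "mean"
#' @return named numeric vector, ligand_ref -> aggregated score (failed
#'   tasks excluded)
#' @export
aggregate_scores <- function(results, aggregate = c("best", "mean")) {
  aggregate <- match.arg(aggregate)
  ok <- results[results$status == "ok", , drop = FALSE]
  fn <- if (aggregate == "best") min else mean
  tapply(ok$score, ok$ligand_ref, fn)
}
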