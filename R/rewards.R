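#' @name rewards
#' @title Multi-objective reward: property gate, toxicophore screen,
#'   activity classifier
#'
#' @description
#' The reward layer scores a generated structure in three stages. First a
#' physicochemical profile is computed (validity indicator E, molecular
#' weight, Crippen logP, topological polar surface area, toxicophore alert
#' count, and optionally ligand efficiency). Second, the property gate
#' checks every configured property against an inclusive `[lower, upper]`
#' range; the shipped defaults are MW 200-500 Da, logP 1.5-5.5, TPSA
#' 40-120 A^2 and at most 2 toxicophore alerts. Third, a perceptron over
#' docking-derived features (score, heavy-atom count, score/heavy-atom
#' ratio) predicts bioactivity. The total reward is a weighted sum: a base
#' validity term, a bonus per in-range property, a full-gate bonus and an
#' activity bonus; an invalid molecule always scores 0.
#'
#' Ligand efficiency is not given a formula by the range table; here it is
#' defined as `-score / heavy_atoms` (the standard convention) and is only
#' gated when docking is enabled.
NULL

#' Default property ranges
#'
#' Inclusive target ranges for the multi-objective gate: MW 200-500,
#' logP 1.5-5.5, TPSA 40-120, toxicophores 0-2.
#' @return named list of `c(lower, upper)` ranges
#' @export
default_property_ranges <- function() {
  list(MW = c(200, 500), logP = c(1.5, 5.5), TPSA = c(40, 120),
       toxicophores = c(0, 2))
}

default_toxicophores <- function() {
  path <- system.file("extdata", "toxicophores.smarts", package = "fragrl")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Count toxicophore alerts in a molecule
#'
#' Number of distinct screen patterns with at least one substructure match
#' (match multiplicity is not counted).
#'
#' @param smiles character vector of valid molecules
#' @param screen character vector of SMARTS patterns; default is the
#'   bundled structural-alert list
#' @return integer vector of matched-pattern counts
#' @export
toxicophore_count <- function(smiles, screen = default_toxicophores()) {
  if (length(screen) == 0L) return(rep(0L, length(smiles)))
  res <- chem_smarts(smiles, screen)
  vapply(res, function(x) {
    if (is.null(x)) stop("invalid molecule in toxicophore screen")
    sum(unlist(x) > 0L)
  }, integer(1))
}

#' Physicochemical property profile of a structure
#'
#' @param smiles a single structure string
#' @param screen toxicophore SMARTS screen
#' @return a `fragrl_profile`: list with E (0/1 validity), MW, logP, PSA,
#'   T (alert count) and LE (NA unless supplied by the docking layer)
#' @export
#' @examples \dontrun{compute_properties("c1ccccc1")  # MW ~ 78.11}
compute_properties <- function(smiles, screen = default_toxicophores()) {
  stopifnot(length(smiles) == 1L)
  d <- chem_descriptors(smiles)[[1]]
  if (!isTRUE(d$valid)) {
    return(structure(list(E = 0L, MW = NA_real_, logP = NA_real_,
                          PSA = NA_real_, T = NA_integer_, LE = NA_real_),
                     class = "fragrl_profile"))
  }
  structure(list(E = 1L, MW = d$mw, logP = d$logp, PSA = d$tpsa,
                 T = toxicophore_count(smiles, screen), LE = NA_real_),
            class = "fragrl_profile")
}

#' Multi-objective property gate
#'
#' TRUE iff every configured property lies inside its inclusive
#' `[lower, upper]` range. Properties whose profile value is NA (e.g. LE
#' with docking disabled) are gated only if a range is configured for them.
#'
#' @param profile a `fragrl_profile` of a valid molecule (E = 1)
#' @param ranges named list of `c(lower, upper)`; names among MW, logP,
#'   TPSA, toxicophores, LE
#' @return logical
#' @export
property_gate <- function(profile, ranges = default_property_ranges()) {
  if (!identical(profile$E, 1L) && !identical(profile$E, 1)) return(FALSE)
  all(property_in_range(profile, ranges))
}

# per-property inclusive bound check, named logical vector
property_in_range <- function(profile, ranges) {
  key <- c(MW = "MW", logP = "logP", TPSA = "PSA", toxicophores = "T",
           LE = "LE")
  vapply(names(ranges), function(nm) {
    fld <- key[[nm]]
    v <- profile[[fld]]
    r <- ranges[[nm]]
    stopifnot(r[1] <= r[2])
    if (is.na(v)) stop("property ", nm, " is not available in this profile")
    v >= r[1] && v <= r[2]
  }, logical(1))
}

#' Docking-derived activity features
#'
#' The three perceptron inputs: docking score, non-hydrogen atom count and
#' their ratio.
#'
#' @param score docking score (more negative = better)
#' @param heavy_atoms non-hydrogen atom count, >= 1
#' @return a `fragrl_docking_features` list (score, heavy_atoms, ratio)
#' @export
docking_features <- function(score, heavy_atoms) {
  if (any(heavy_atoms < 1L)) stop("heavy_atoms must be >= 1")
  structure(list(score = score, heavy_atoms = as.integer(heavy_atoms),
                 ratio = score / heavy_atoms),
            class = "fragrl_docking_features")
}

features_matrix <- function(feats) {
  if (inherits(feats, "fragrl_docking_features")) {
    cbind(score = feats$score, heavy_atoms = feats$heavy_atoms,
          ratio = feats$ratio)
  } else {
    do.call(rbind, lapply(feats, function(f) {
      c(score = f$score, heavy_atoms = f$heavy_atoms, ratio = f$ratio)
    }))
  }
}

#' Train the perceptron activity classifier
#'
#' Classic perceptron updates (`w <- w + lr * y * x` on each misclassified
#' sample) on z-standardized features, cycling the samples in order for a
#' fixed number of epochs. Deterministic under a fixed seed (used only for
#' the tiny random weight initialization).
#'
#' @param feats a `fragrl_docking_features` with vector fields, or a list of
#'   single-sample feature objects
#' @param labels logical or 0/1 vector, TRUE/1 = active
#' @param epochs passes over the data
#' @param lr learning rate
#' @param seed integer seed
#' @return a `fragrl_perceptron`: weights (length 3), bias,
#'   standardization (center/scale), and training accuracy
#' @export
train_perceptron <- function(feats, labels, epochs = 100L, lr = 0.1,
                             seed = 1L) {
  x <- features_matrix(feats)
  y <- ifelse(as.logical(labels), 1, -1)
  stopifnot(nrow(x) == length(y))
  if (length(unique(y)) < 2L) {
    stop("both classes (active and inactive) must be present")
  }
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  rng <- rng_stream(seed)
  w <- rng$runif(ncol(x), -1e-3, 1e-3)
  b <- 0
  for (ep in seq_len(epochs)) {
    misses <- 0L
    for (i in seq_len(nrow(xs))) {
      pred <- sum(w * xs[i, ]) + b
      if (y[i] * pred <= 0) {
        w <- w + lr * y[i] * xs[i, ]
        b <- b + lr * y[i]
        misses <- misses + 1L
      }
    }
    if (misses == 0L) break
  }
  pred <- as.vector(xs %*% w + b) > 0
  structure(list(weights = w, bias = b, center = center, scale = scale,
                 train_accuracy = mean(pred == (y > 0))),
            class = "fragrl_perceptron")
}

#' Predict activity with a trained perceptron
#'
#' @param model a `fragrl_perceptron`
#' @param feats docking features (vectorized or a list)
#' @return logical vector, TRUE = predicted active (weighted sum + bias > 0)
#' @export
predict_activity <- function(model, feats) {
  x <- features_matrix(feats)
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  as.vector(xs %*% model$weights + model$bias) > 0
}

#' Default reward weights
#' @return named list: validity 0.1, per in-range property 0.15, full gate
#'   0.2, predicted activity 0.3
#' @export
default_reward_weights <- function() {
  list(validity = 0.1, property = 0.15, gate = 0.2, activity = 0.3)
}

#' Total multi-objective reward of a structure
#'
#' Invalid molecules score 0. Valid molecules receive the validity term
#' plus, when property optimization is enabled, one bonus per in-range
#' property, a full-gate bonus, and an activity bonus if an activity
#' oracle predicts active. Monotone: satisfying one more criterion never
#' lowers the total.
#'
#' @param smiles structure string
#' @param ranges property ranges (see [default_property_ranges()])
#' @param weights reward weights (see [default_reward_weights()])
#' @param activity_fn optional function(smiles) -> logical, e.g. a trained
#'   perceptron over docking-farm scores; NULL disables the activity term
#' @param use_property_optimization ablation switch: FALSE disables the
#'   property and activity terms, leaving the validity term only
#' @param screen toxicophore SMARTS screen
#' @return a `fragrl_reward`: validity_reward, property_reward,
#'   activity_reward, gate_pass, total
#' @export
total_reward <- function(smiles, ranges = default_property_ranges(),
                         weights = default_reward_weights(),
                         activity_fn = NULL,
                         use_property_optimization = TRUE,
                         screen = default_toxicophores()) {
  zero <- structure(list(validity_reward = 0, property_reward = 0,
                         activity_reward = 0, gate_pass = FALSE, total = 0),
                    class = "fragrl_reward")
  if (is.na(smiles) || !check_validity(smiles)) return(zero)
  validity_reward <- weights$validity
  property_reward <- 0
  activity_reward <- 0
  gate_pass <- FALSE
  if (isTRUE(use_property_optimization)) {
    profile <- compute_properties(smiles, screen)
    inr <- property_in_range(profile, ranges)
    gate_pass <- all(inr)
    property_reward <- weights$property * sum(inr) +
      if (gate_pass) weights$gate else 0
    if (!is.null(activity_fn) && isTRUE(activity_fn(smiles))) {
      activity_reward <- weights$activity
    }
  }
  structure(list(validity_reward = validity_reward,
                 property_reward = property_reward,
                 activity_reward = activity_reward,
                 gate_pass = gate_pass,
                 total = validity_reward + property_reward + activity_reward),
            class = "fragrl_reward")
}
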