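#' @name metrics
#' @title Generation-quality metrics
#'
#' @description
#' The benchmark metric suite for generated molecule sets: validity,
#' uniqueness and novelty fractions (canonical-SMILES comparison), internal
#' diversity `IntDiv_p(G) = 1 - ((1/|G|^2) * sum over ordered pairs of
#' T(m1, m2)^p)^(1/p)` with `T` the Morgan-fingerprint Tanimoto similarity
#' (self-pairs included, following the literal sum over G x G),
#' Bemis-Murcko scaffold-frequency cosine similarity, and the Frechet
#' distance between Gaussian moment summaries of activation features,
#' `||mu_G - mu_R||^2 + Tr(S_G + S_R - 2 (S_G S_R)^(1/2))`. SA (synthetic
#' accessibility, 1-10, lower = easier) and QED (drug-likeness, 0-1) are
#' reported per molecule.
#'
#' The default Frechet feature extractor is a synthetic stand-in (folded
#' fingerprint count bins plus scaled MW/logP/TPSA); reproducing published
#' numbers from the trained ChemNet activations is explicitly not claimed —
#' plug in another extractor for that.
NULL

#' Validity fraction of a generated set
#' @param g character vector of structure strings
#' @return fraction in `[0, 1]`
#' @export
validity_fraction <- function(g) {
  stopifnot(length(g) > 0L)
  mean(check_validity(g))
}

#' Uniqueness fraction of a validity-filtered set
#' @param g_valid character vector of valid structures
#' @return distinct canonical structures / set size
#' @export
uniqueness_fraction <- function(g_valid) {
  stopifnot(length(g_valid) > 0L)
  length(unique(chem_canonical(g_valid))) / length(g_valid)
}

#' Novelty fraction relative to a training set
#' @param g_valid character vector of valid structures
#' @param reference training-set structures
#' @return fraction of canonical structures absent from the reference
#' @export
novelty_fraction <- function(g_valid, reference) {
  g <- chem_canonical(g_valid)
  r <- unique(chem_canonical(reference))
  mean(!(g %in% r))
}

# pairwise fingerprint Tanimoto over on-bit sets, including the diagonal
tanimoto_matrix <- function(fps) {
  n <- length(fps)
  m <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        inter <- length(intersect(fps[[i]], fps[[j]]))
        uni <- length(fps[[i]]) + length(fps[[j]]) - inter
        m[i, j] <- m[j, i] <- if (uni == 0L) 0 else inter / uni
      }
    }
  }
  m
}

#' Internal diversity of a generated set
#'
#' `1 - (mean over all ordered pairs, self-pairs included, of T^p)^(1/p)`.
#' A singleton or duplicate-only set scores 0.
#'
#' @param g_valid character vector of valid structures
#' @param p positive integer power (1 or 2 in the benchmarks)
#' @param nbits,radius Morgan fingerprint parameters
#' @return value in `[0, 1]`
#' @export
internal_diversity <- function(g_valid, p = 1L, nbits = 2048L,
                               radius = 2L) {
  stopifnot(length(g_valid) >= 1L, p >= 1)
  fps <- chem_fingerprint(chem_canonical(g_valid), nbits, radius)
  intdiv_from_tanimoto(tanimoto_matrix(fps), p)
}

# the power-mean identity on an explicit Tanimoto matrix
intdiv_from_tanimoto <- function(tm, p) {
  1 - mean(tm^p)^(1 / p)
}

scaffold_counts <- function(smiles) {
  sc <- bemis_murcko_scaffold(smiles)
  sc <- sc[nzchar(sc)]  # acyclic molecules contribute no scaffold
  table(sc)
}

#' Bemis-Murcko scaffold cosine similarity between two sets
#'
#' Cosine of the scaffold-frequency vectors over the union of scaffolds in
#' either set. If neither set contains a ring system the metric is defined
#' as 0 (with a warning).
#'
#' @param g,r character vectors of valid structures
#' @return value in `[0, 1]`
#' @export
scaffold_similarity <- function(g, r) {
  stopifnot(length(g) > 0L, length(r) > 0L)
  cg <- scaffold_counts(g)
  cr <- scaffold_counts(r)
  s <- union(names(cg), names(cr))
  if (length(s) == 0L) {
    warning("no scaffolds in either set; scaffold similarity defined as 0")
    return(0)
  }
  vg <- as.numeric(cg[s]); vg[is.na(vg)] <- 0
  vr <- as.numeric(cr[s]); vr[is.na(vr)] <- 0
  denom <- sqrt(sum(vg^2)) * sqrt(sum(vr^2))
  if (denom == 0) return(0)
  sum(vg * vr) / denom
}

# symmetric PSD square root via eigendecomposition, clipping small negative
# eigenvalues that arise from rounding
sym_sqrt <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Frechet distance between two feature clouds
#'
#' `||mu_G - mu_R||^2 + Tr(S_G + S_R - 2 (S_G S_R)^(1/2))` with full
#' covariance matrices; the matrix square root uses a symmetric
#' eigendecomposition with negative-eigenvalue clipping.
#'
#' @param feats_g,feats_r numeric matrices (rows = molecules, columns =
#'   features), at least 2 rows each
#' @return non-negative distance
#' @export
frechet_distance <- function(feats_g, feats_r) {
  feats_g <- as.matrix(feats_g); feats_r <- as.matrix(feats_r)
  stopifnot(nrow(feats_g) >= 2L, nrow(feats_r) >= 2L,
            ncol(feats_g) == ncol(feats_r))
  if (any(!is.finite(feats_g)) || any(!is.finite(feats_r))) {
    stop("non-finite features")
  }
  mu_g <- colMeans(feats_g); mu_r <- colMeans(feats_r)
  s_g <- stats::cov(feats_g); s_r <- stats::cov(feats_r)
  rg <- sym_sqrt(s_g)
  cross <- sym_sqrt(rg %*% s_r %*% rg)  # same trace as (S_G S_R)^(1/2)
  d <- sum((mu_g - mu_r)^2) + sum(diag(s_g)) + sum(diag(s_r)) -
    2 * sum(diag(cross))
  max(d, 0)
}

#' Default Frechet feature extractor (synthetic stand-in)
#'
#' Folds the 2048-bit Morgan fingerprint into `bins` on-bit count bins and
#' appends MW/100, logP and TPSA/100. Deterministic, fixed width; not a
#' ChemNet replacement.
#'
#' @param smiles character vector of valid structures
#' @param bins number of fingerprint fold bins
#' @return numeric matrix, `length(smiles)` x `(bins + 3)`
#' @export
fcd_features <- function(smiles, bins = 16L) {
  fps <- chem_fingerprint(smiles)
  desc <- chem_descriptors(smiles)
  t(vapply(seq_along(smiles), function(i) {
    counts <- tabulate((fps[[i]] %% bins) + 1L, nbins = bins)
    d <- desc[[i]]
    if (!isTRUE(d$valid)) stop("invalid molecule in feature extraction")
    c(counts, d$mw / 100, d$logp, d$tpsa / 100)
  }, numeric(bins + 3L)))
}

#' Synthetic accessibility score
#' @param smiles character vector of valid molecules
#' @return numeric scores in `[1, 10]`, lower = easier to synthesize
#' @export
sa_score <- function(smiles) {
  out <- chem_sa(smiles)
  if (anyNA(out)) stop("invalid molecule passed to sa_score")
  out
}

#' Quantitative estimate of drug-likeness (QED)
#' @param smiles character vector of valid molecules
#' @return numeric scores in `[0, 1]`
#' @export
qed_score <- function(smiles) {
  out <- chem_qed(smiles)
  if (anyNA(out)) stop("invalid molecule passed to qed_score")
  out
}

#' Full generation-metric record
#'
#' @param g generated structures
#' @param reference training/reference structures
#' @param p_values powers for internal diversity
#' @param features feature extractor for the Frechet distance
#' @return a `fragrl_metrics` list: validity, uniqueness, novelty,
#'   intdiv (named by p), scaff_sim, fcd, plus mean SA and QED of the
#'   valid generated molecules
#' @export
generation_metrics <- function(g, reference, p_values = c(1L, 2L),
                               features = fcd_features) {
  validity <- validity_fraction(g)
  g_valid <- g[check_validity(g)]
  if (length(g_valid) == 0L) stop("no valid molecules to score")
  intdiv <- vapply(p_values, function(p) internal_diversity(g_valid, p),
                   numeric(1))
  names(intdiv) <- paste0("p", p_values)
  structure(list(
    validity = validity,
    uniqueness = uniqueness_fraction(g_valid),
    novelty = novelty_fraction(g_valid, reference),
    intdiv = intdiv,
    scaff_sim = scaffold_similarity(g_valid, reference),
    fcd = frechet_distance(features(unique(chem_canonical(g_valid))),
                           features(unique(chem_canonical(reference)))),
    sa_mean = mean(sa_score(g_valid)),
    qed_mean = mean(qed_score(g_valid))),
    class = "fragrl_metrics")
}

#' @export
print.fragrl_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<generation metrics>\n",
    "  validity   %.3f\n  uniqueness %.3f\n  novelty    %.3f\n",
    "  intdiv     %s\n  scaff_sim  %.3f\n  fcd        %.3f\n",
    "  SA mean    %.2f\n  QED mean   %.3f\n"),
    x$validity, x$uniqueness, x$novelty,
    paste(sprintf("%s=%.3f", names(x$intdiv), x$intdiv), collapse = " "),
    x$scaff_sim, x$fcd, x$sa_mean, x$qed_mean))
  invisible(x)
}
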