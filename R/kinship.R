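#' Pedigree additive relationship matrix for half-sib families
#'
#' One-generation open-pollinated assumption: diagonal 1 (non-inbred),
#' 0.25 between maternal half-sibs, 0 across families.
#'
#' @param pedigree data.frame with columns `id` and `mother`.
#' @return [KinshipMatrix-class] with method `"pedigree_A"`.
#' @export
pedigreeA <- function(pedigree) {
  if (anyNA(pedigree$mother) || any(pedigree$mother == ""))
    stop("individual(s) with no family label")
  fam <- as.character(pedigree$mother)
  A <- 0.25 * outer(fam, fam, "==")
  diag(A) <- 1
  dimnames(A) <- list(pedigree$id, pedigree$id)
  KinshipMatrix(A, "pedigree_A")
}

#' VanRaden genomic relationship matrix
#'
#' `G = W W' / (2 * sum(p_k (1 - p_k)))` with `W` the dosage matrix centered
#' by twice the observed allele frequency per marker. Monomorphic markers
#' contribute nothing (zero centered column, zero variance term).
#'
#' @param g [GenotypeData-class] with no missing dosages (run
#'   [imputeMean()] first) or a complete dosage matrix.
#' @return [KinshipMatrix-class] with method `"vanraden"`.
#' @export
grmVanRaden <- function(g) {
  M <- if (is(g, "GenotypeData")) dosages(g) else g
  if (anyNA(M)) stop("missing dosages: impute first")
  pk <- colMeans(M) / 2
  denom <- 2 * sum(pk * (1 - pk))
  if (denom == 0) stop("all markers monomorphic")
  W <- sweep(M, 2, 2 * pk)
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  KinshipMatrix(G, "vanraden")
}

#' Powell unified-relatedness genomic relationship matrix
#'
#' Allele-frequency-standardized identity averaged across loci
#' (the Powell-Visscher-Balding unified estimator, as implemented in
#' whole-genome tools): off-diagonals
#' `mean_k (x_jk - 2 p_k)(x_ik - 2 p_k) / (2 p_k (1 - p_k))` and diagonals
#' `1 + mean_k (x_jk^2 - (1 + 2 p_k) x_jk + 2 p_k^2) / (2 p_k (1 - p_k))`.
#' Used here for LD kinship corrections.
#'
#' @inheritParams grmVanRaden
#' @return [KinshipMatrix-class] with method `"powell"`.
#' @export
grmPowell <- function(g) {
  M <- if (is(g, "GenotypeData")) dosages(g) else g
  if (anyNA(M)) stop("missing dosages: impute first")
  pk <- colMeans(M) / 2
  keep <- pk > 0 & pk < 1
  if (!any(keep)) stop("all markers monomorphic")
  M <- M[, keep, drop = FALSE]
  pk <- pk[keep]
  het <- 2 * pk * (1 - pk)
  Ws <- sweep(sweep(M, 2, 2 * pk), 2, sqrt(het), "/")
  G <- tcrossprod(Ws) / length(pk)
  diag(G) <- 1 + colMeans((t(M)^2 - (1 + 2 * pk) * t(M) + 2 * pk^2) / het)
  dimnames(G) <- list(rownames(M), rownames(M))
  KinshipMatrix(G, "powell")
}

#' Principal components of the genomic relationship
#'
#' Eigen-decomposition of the VanRaden GRM (equivalent to the SVD of the
#' centered, frequency-scaled dosages): scores are
#' `U_k sqrt(lambda_k)`, orthogonal with non-increasing eigenvalues.
#'
#' @param g [GenotypeData-class] (imputed) or a [KinshipMatrix-class].
#' @param n_components number of leading components to return.
#' @return list with `scores` (n x k matrix), `eigenvalues` (all n), and
#'   `varprop` (fraction of trace per returned component).
#' @export
genoPca <- function(g, n_components = 10) {
  G <- if (is(g, "KinshipMatrix")) as.matrix(g)
       else as.matrix(grmVanRaden(imputeMean(g)))
  if (n_components > nrow(G)) stop("n_components exceeds sample count")
  ee <- eigen(G, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  k <- seq_len(n_components)
  scores <- ee$vectors[, k, drop = FALSE] %*% diag(sqrt(lam[k]), n_components)
  dimnames(scores) <- list(rownames(G), paste0("PC", k))
  list(scores = scores, eigenvalues = ee$values,
       varprop = lam[k] / sum(lam))
}

#' Relatedness-minimized or random train/validation split
#'
#' `mode = "unrelated"`: individuals with any leading-PC score beyond
#' `outlier_sd` standard deviations are set aside, k-means (k = 2) on the
#' leading `n_pcs` PCs defines two clusters, and the larger cluster becomes
#' the training set -- maximizing genetic distance between sets.
#' `mode = "random"`: a uniformly random split into the same set sizes,
#' the control that keeps relatedness between sets.
#'
#' @param scores PC score matrix from [genoPca()] (rownames = ids).
#' @param mode `"unrelated"` or `"random"`.
#' @param n_pcs leading PCs used for outliers and clustering.
#' @param outlier_sd outlier threshold in per-PC standard deviations.
#' @param sizes optional `c(train, valid)` sizes for the random mode.
#' @param seed optional seed.
#' @return list (`SplitPlan`): `train_ids`, `valid_ids`, `basis`,
#'   `excluded_outliers`.
#' @export
makeSplit <- function(scores, mode = c("unrelated", "random"), n_pcs = 2,
                      outlier_sd = 6, sizes = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(scores)
  if (mode == "random") {
    if (is.null(sizes)) sizes <- c(ceiling(length(ids) / 2),
                                   floor(length(ids) / 2))
    pick <- sample(ids, sizes[1])
    rest <- setdiff(ids, pick)
    return(list(train_ids = pick, valid_ids = rest[seq_len(min(sizes[2],
                 length(rest)))], basis = "random",
                excluded_outliers = character(0)))
  }
  S <- scores[, seq_len(min(n_pcs, ncol(scores))), drop = FALSE]
  z <- abs(scale(S))
  out <- apply(z, 1, max) > outlier_sd
  keep <- ids[!out]
  km <- kmeans(S[!out, , drop = FALSE], centers = 2, nstart = 10)
  if (min(table(km$cluster)) == 0) stop("degenerate cluster sizes")
  big <- which.max(tabulate(km$cluster))
  list(train_ids = keep[km$cluster == big],
       valid_ids = keep[km$cluster != big],
       basis = "pca_clusters", excluded_outliers = ids[out])
}

#' Write a split plan as JSON
#' @param plan a split plan from [makeSplit()]
#' @param path output path
#' @export
writeSplitPlan <- function(plan, path) {
  jsonlite::write_json(plan, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
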