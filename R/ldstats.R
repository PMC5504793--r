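#' Pairwise linkage disequilibrium with kinship / structure corrections
#'
#' For every within-chromosome marker pair up to `max_dist_bp`, computes the
#' classical `r^2` (squared Pearson correlation of dosage vectors) and, on
#' request, corrected variants in the Mangin style: `r^2_S` squares the
#' correlation of dosages with the structure covariates regressed out,
#' `r^2_V` whitens dosages by the inverse symmetric square root of a
#' kinship matrix, and `r^2_VS` applies both (projection first, then
#' whitening). Missing calls are mean-imputed before correlation.
#'
#' @param g [GenotypeData-class]
#' @param max_dist_bp maximum pair distance in bp.
#' @param corrections subset of `c("V", "S", "VS")`; empty gives raw only.
#' @param kinship [KinshipMatrix-class] (Powell construction recommended),
#'   required for `"V"`/`"VS"`.
#' @param struct_covar matrix/vector of structure covariates (e.g. leading
#'   PC scores or a cluster indicator), required for `"S"`/`"VS"`.
#' @param eig_floor eigenvalue floor applied when inverting the kinship
#'   square root; near-singular GRMs are ridge-stabilized with a warning.
#' @return `data.frame` (LDTable) with columns `chrom`, `pos_i`, `pos_j`,
#'   `dist_bp`, `r2` and one column per requested correction (`r2_v`,
#'   `r2_s`, `r2_vs`).
#' @export
pairwiseLD <- function(g, max_dist_bp = 1e5, corrections = character(0),
                       kinship = NULL, struct_covar = NULL,
                       eig_floor = 1e-8) {
  stopifnot(all(corrections %in% c("V", "S", "VS")))
  M <- dosages(imputeMean(g))
  mm <- g@map
  needV <- any(c("V", "VS") %in% corrections)
  needS <- any(c("S", "VS") %in% corrections)
  if (needV && is.null(kinship)) stop("kinship required for V/VS corrections")
  if (needS && is.null(struct_covar))
    stop("struct_covar required for S/VS corrections")
  Vearg <- NULL
  if (needV) {
    K <- as.matrix(kinship)
    ee <- eigen(K, symmetric = TRUE)
    lam <- pmax(ee$values, 0)
    if (min(ee$values) < eig_floor) {
      # frequency-centered GRMs are singular by construction (K 1 = 0);
      # a proportional ridge bounds the whitening amplification
      ridge <- 0.01 * mean(diag(K))
      warning("kinship near-singular; ridge ", signif(ridge, 3), " added")
      lam <- lam + ridge
    }
    Vearg <- ee$vectors %*% (t(ee$vectors) / sqrt(lam))  # K^{-1/2}
  }
  projOff <- function(X, C) qr.resid(qr(C), X)  # rank-deficiency safe
  # GLS construction: whiten genotypes AND the nuisance design (intercept,
  # structure covariates) by K^{-1/2}, then residualize the genotypes on
  # the whitened design before correlating -- plain projection when no
  # kinship is involved
  ones <- matrix(1, nrow(M), 1)
  transforms <- list(none = M)
  if ("V" %in% corrections)
    transforms$V <- projOff(Vearg %*% M, Vearg %*% ones)
  if ("S" %in% corrections)
    transforms$S <- projOff(M, cbind(ones, as.matrix(struct_covar)))
  if ("VS" %in% corrections)
    transforms$VS <- projOff(Vearg %*% M,
                             Vearg %*% cbind(ones, as.matrix(struct_covar)))
  res <- lapply(split(seq_len(nrow(mm)), mm$chrom), function(idx) {
    if (length(idx) < 2) return(NULL)
    pos <- mm$pos_bp[idx]
    pr <- which(outer(pos, pos, function(a, b) b - a) > 0 &
                outer(pos, pos, function(a, b) abs(b - a)) <= max_dist_bp,
                arr.ind = TRUE)
    if (nrow(pr) == 0) return(NULL)
    out <- data.frame(chrom = mm$chrom[idx[1]],
                      pos_i = pos[pr[, 1]], pos_j = pos[pr[, 2]],
                      dist_bp = pos[pr[, 2]] - pos[pr[, 1]])
    for (nm in names(transforms)) {
      cc <- suppressWarnings(cor(transforms[[nm]][, idx, drop = FALSE]))
      col <- cc[pr]^2
      out[[if (nm == "none") "r2" else paste0("r2_", tolower(nm))]] <- col
    }
    out
  })
  out <- do.call(rbind, Filter(Negate(is.null), res))
  rownames(out) <- NULL
  out
}

# Hill-Weir drift-sampling expectation of r^2 at recombination scale C and
# sample size n (the Marroni-style formulation used for decay fitting).
.hillWeir <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the LD decay curve and locate the r2 threshold distance
#'
#' Nonlinear least squares of the Hill-Weir drift-sampling expectation of
#' `r^2` as a function of `C = c_per_bp * dist` at sample size `n`, with
#' three log-spaced starting values; the best converged fit by residual sum
#' of squares wins. The distance where the fitted curve crosses `level` is
#' solved numerically; if the curve stays above `level` out to ten times
#' the largest observed distance, the threshold is reported unbounded
#' (`Inf`).
#'
#' @param ld LDTable from [pairwiseLD()].
#' @param n sample size entering the expectation.
#' @param level the `r^2` threshold (default 0.2).
#' @param stat which LD column to fit (default `"r2"`).
#' @return list (DecayFit): `n_used`, `c_per_bp`, `d_threshold_bp`,
#'   `level`, `rss`, `n_pairs`.
#' @export
fitLdDecay <- function(ld, n, level = 0.2, stat = "r2") {
  d <- ld$dist_bp
  y <- ld[[stat]]
  keep <- is.finite(y) & is.finite(d) & d > 0
  d <- d[keep]; y <- y[keep]
  if (length(d) < 50) stop("need at least 50 pairs spanning a distance range")
  starts <- 10^seq(log10(0.01 / max(d)), log10(100 / max(d)), length.out = 3)
  fits <- lapply(starts, function(s0) {
    tryCatch(minpack.lm::nlsLM(y ~ .hillWeir(cpb * d, n),
                               start = list(cpb = s0),
                               lower = 1e-16, control = list(maxiter = 200)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("decay fit failed to converge from all starts")
  rss <- vapply(fits, function(f) sum(resid(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cpb <- coef(best)[["cpb"]]
  f <- function(x) .hillWeir(cpb * x, n) - level
  dmax <- 10 * max(d)
  dThr <- if (f(dmax) > 0) Inf
          else if (f(.Machine$double.eps) < 0) 0
          else uniroot(f, c(.Machine$double.eps, dmax), tol = 1e-3)$root
  list(n_used = n, c_per_bp = cpb, d_threshold_bp = dThr, level = level,
       rss = min(rss), n_pairs = length(d))
}

#' LD-based effective population size (LDNe)
#'
#' Estimates Ne from the mean squared dosage correlation over
#' inter-chromosomal (physically unlinked) marker pairs, after excluding
#' rare alleles at `maf_cutoff`. The sampling expectation is subtracted per
#' the bias-corrected random-mating estimator for samples of S >= 30
#' individuals (Waples-style constants):
#' `E[r^2 | S] = 1/S + 3.19/S^2`, and
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')` with
#' `r2' = mean(r^2) - E[r^2 | S]`. The parametric confidence interval
#' treats the number of independent comparisons as chi-square degrees of
#' freedom on the mean r^2 before re-applying the transformation.
#'
#' @param g [GenotypeData-class] (unphased dosages accepted; missing calls
#'   are mean-imputed).
#' @param maf_cutoff markers with MAF below this are excluded (default
#'   0.05, i.e. rare alleles removed).
#' @param max_pairs cap on the number of inter-chromosomal pairs used.
#' @param alpha CI level (two-sided).
#' @param seed optional seed for pair subsampling.
#' @return list (NeEstimate): `ne_hat`, `ci_low`, `ci_high`, `r2_mean`,
#'   `r2_drift`, `n_pairs`, `s_size`, `maf_cutoff`. `ne_hat = Inf` flags an
#'   adjusted mean r^2 at or below zero (no detectable drift LD).
#' @export
estimateNe <- function(g, maf_cutoff = 0.05, max_pairs = 5000,
                       alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mm <- markerMap(g)
  keep <- !is.na(mm$maf) & mm$maf >= maf_cutoff
  if (sum(keep) < 2) stop("fewer than 2 markers after MAF exclusion")
  gg <- g[, which(keep)]
  if (length(unique(gg@map$chrom)) < 2)
    stop("inter-chromosomal Ne estimation needs at least 2 chromosomes")
  M <- dosages(imputeMean(gg))
  chrom <- gg@map$chrom
  pr <- which(outer(chrom, chrom, "!=") & upper.tri(diag(length(chrom))),
              arr.ind = TRUE)
  if (nrow(pr) > max_pairs)
    pr <- pr[sample.int(nrow(pr), max_pairs), , drop = FALSE]
  cc <- cor(M[, unique(c(pr))])
  # map pair indices into the reduced correlation matrix
  lut <- match(seq_len(ncol(M)), unique(c(pr)))
  r2 <- cc[cbind(lut[pr[, 1]], lut[pr[, 2]])]^2
  S <- nrow(M)
  if (S < 30) warning("sample size below 30; small-sample constants not implemented")
  expS <- 1 / S + 3.19 / S^2
  toNe <- function(r2bar) {
    rp <- r2bar - expS
    if (!is.finite(rp) || rp <= 0) return(Inf)
    disc <- 1 / 9 - 2.76 * rp
    if (disc < 0) return((1 / 3) / (2 * rp))  # very small Ne limit
    (1 / 3 + sqrt(disc)) / (2 * rp)
  }
  r2bar <- mean(r2)
  df <- length(r2)
  lowR2 <- r2bar * df / qchisq(1 - alpha / 2, df)
  highR2 <- r2bar * df / qchisq(alpha / 2, df)
  list(ne_hat = toNe(r2bar), ci_low = toNe(highR2), ci_high = toNe(lowR2),
       r2_mean = r2bar, r2_drift = r2bar - expS, n_pairs = df, s_size = S,
       maf_cutoff = maf_cutoff)
}

#' Write an LD table as TSV
#' @param ld LDTable data.frame
#' @param path output path
#' @export
writeLdTable <- function(ld, path) {
  write.table(ld, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
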