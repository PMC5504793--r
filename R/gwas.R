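# vectorized per-SNP OLS/GLS after projecting covariates out; rows of M
# and y are assumed pre-rotated/weighted by the caller for the GLS case
.scanCore <- function(y, C, M) {
  n <- length(y)
  q <- qr(C)
  yr <- qr.resid(q, y)
  Mr <- qr.resid(q, M)
  xtx <- colSums(Mr^2)
  ok <- xtx > 1e-10
  beta <- se <- p <- rep(NA_real_, ncol(M))
  beta[!ok] <- 0; p[!ok] <- 1
  xty <- colSums(Mr * yr)
  b <- xty[ok] / xtx[ok]
  dfr <- n - q$rank - 1
  rss <- sum(yr^2) - b^2 * xtx[ok]
  s2 <- pmax(rss, 0) / dfr
  seOk <- sqrt(s2 / xtx[ok])
  tt <- b / seOk
  beta[ok] <- b
  se[ok] <- seOk
  p[ok] <- 2 * pt(-abs(tt), dfr)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(beta = beta, se = se, p = p, flagged = !ok)
}

.lambdaGC <- function(p) {
  median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)
}

.gwasTable <- function(g, core, model, alpha = 0.05, fdr = 0.05) {
  mm <- markerMap(g)
  adj <- adjustPvalues(core$p, alpha = alpha, fdr = fdr)
  out <- data.frame(marker = mm$marker, chrom = mm$chrom, pos_bp = mm$pos_bp,
                    maf = mm$maf, beta = core$beta, se = core$se,
                    p = core$p, p_bonf = adj$p_bonf, q_bh = adj$q_bh,
                    sig_bonf = adj$sig_bonf, sig_bh = adj$sig_bh,
                    flagged = core$flagged)
  attr(out, "lambda_gc") <- .lambdaGC(core$p)
  attr(out, "model") <- model
  class(out) <- c("GWASResult", "data.frame")
  out
}

#' Genomic inflation factor of a scan
#' @param x a `GWASResult` (or any object with a `lambda_gc` attribute)
#' @return scalar lambda_gc (median observed chi-square over its null
#'   expectation 0.4549)
#' @export
lambdaGC <- function(x) attr(x, "lambda_gc")

#' Single-SNP linear-model association scan (LMA)
#'
#' Ordinary least squares per SNP: the dosage enters as a fixed covariate
#' next to the supplied covariates (intercept + blocks, optionally a
#' structure covariate), with a two-sided Wald test. Monomorphic or
#' covariate-collinear SNPs are flagged and returned with `beta = 0`,
#' `p = 1`.
#'
#' @param y phenotype vector.
#' @param covariates covariate design matrix (include the intercept) --
#'   e.g. from the internal block-design helper.
#' @param g [GenotypeData-class]; missing calls mean-imputed.
#' @param alpha,fdr thresholds for the Bonferroni / Benjamini-Hochberg
#'   significance calls.
#' @return `GWASResult` data.frame (per-SNP `beta`, `se`, `p`, `p_bonf`,
#'   `q_bh`, significance calls) with the scan's `lambda_gc` and model tag
#'   as attributes.
#' @export
lmaScan <- function(y, covariates, g, alpha = 0.05, fdr = 0.05) {
  C <- as.matrix(covariates)
  if (qr(C)$rank < ncol(C)) stop("covariate design not full rank")
  M <- dosages(imputeMean(g))
  core <- .scanCore(as.numeric(y), C, M)
  .gwasTable(g, core, "lma", alpha, fdr)
}

#' Mixed-linear-model association scan (MLMA)
#'
#' Variance components of the polygenic model `y = X b + g + e`,
#' `g ~ N(0, G sigma2_g)`, are estimated once under the null (no candidate
#' SNP) by REML; every SNP is then tested as a fixed effect by generalized
#' least squares under the fitted covariance (the candidate remains in the
#' GRM -- plain MLMA, not leave-one-chromosome-out). Computationally the
#' data are rotated to the GRM eigenbasis and weighted, after which the
#' scan reduces to the vectorized OLS core. With `sigma2_g = 0` the scan
#' equals [lmaScan()] exactly.
#'
#' @inheritParams lmaScan
#' @param grm [KinshipMatrix-class] (or matrix), usually VanRaden from all
#'   SNPs.
#' @return `GWASResult` data.frame, as [lmaScan()].
#' @export
mlmaScan <- function(y, covariates, g, grm, alpha = 0.05, fdr = 0.05) {
  C <- as.matrix(covariates)
  if (qr(C)$rank < ncol(C)) stop("covariate design not full rank")
  M <- dosages(imputeMean(g))
  fit <- remlFit(as.numeric(y), C, grm)
  U <- fit$eigenK$U
  sw <- sqrt(1 / (fit$lambda * fit$eigenK$d + 1))
  yt <- sw * crossprod(U, as.numeric(y))
  Ct <- sw * crossprod(U, C)
  Mt <- sw * crossprod(U, M)
  core <- .scanCore(drop(yt), Ct, Mt)
  out <- .gwasTable(g, core, "mlma", alpha, fdr)
  attr(out, "varcomp") <- list(sigma2_g = fit$sigma2_a,
                               sigma2_e = fit$sigma2_e, h2 = fit$h2)
  out
}

#' Multiple-testing adjustment with significance calls
#'
#' Bonferroni (family-wise error at `alpha`) and Benjamini-Hochberg
#' step-up (false discovery rate at `fdr`) adjusted p-values, via
#' [stats::p.adjust()].
#'
#' @param p vector of raw p-values in (0, 1].
#' @param alpha family-wise error level for the Bonferroni call.
#' @param fdr false-discovery rate for the BH call.
#' @return data.frame: `p`, `p_bonf`, `q_bh`, `sig_bonf`, `sig_bh`.
#' @export
adjustPvalues <- function(p, alpha = 0.05, fdr = 0.05) {
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("invalid p-values")
  pb <- p.adjust(p, "bonferroni")
  qb <- p.adjust(p, "BH")
  data.frame(p = p, p_bonf = pb, q_bh = qb,
             sig_bonf = pb <= alpha, sig_bh = qb <= fdr)
}

#' Q-Q and Manhattan summary tables for a scan
#'
#' @param result a `GWASResult`.
#' @return list: `qq` (expected vs observed -log10 p, expected quantiles
#'   `(i - 0.5) / m`), `manhattan` (`chrom`, `pos_bp`, `neglog10p`), and
#'   `lambda_gc`.
#' @export
scanSummaries <- function(result) {
  if (!nrow(result)) stop("empty scan result")
  p <- result$p
  m <- length(p)
  ord <- order(p)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(p[ord]),
                   marker = result$marker[ord])
  man <- data.frame(chrom = result$chrom, pos_bp = result$pos_bp,
                    marker = result$marker, neglog10p = -log10(p))
  list(qq = qq, manhattan = man, lambda_gc = lambdaGC(result))
}

#' Write a GWAS result as TSV
#' @param result `GWASResult`
#' @param path output path
#' @export
writeGwasResult <- function(result, path) {
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
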