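#' @useDynLib treegs, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# design matrix for intercept + block factor; reference level dropped
.blockDesign <- function(block, covar = NULL) {
  X <- stats::model.matrix(~ factor(block))
  if (!is.null(covar)) X <- cbind(X, as.matrix(covar))
  X
}

# indices of a maximal linearly independent column subset
.independentCols <- function(X) {
  q <- qr(X)
  sort(q$pivot[seq_len(q$rank)])
}

#' REML fit of the single-kinship mixed model
#'
#' Fits `y = X b + a + e` with `a ~ N(0, K sigma2_a)`,
#' `e ~ N(0, I sigma2_e)` by restricted maximum likelihood, profiling the
#' variance ratio `lambda = sigma2_a / sigma2_e` on the spectrum of `K`
#' (one eigen-decomposition, then a 1-D search of the restricted
#' likelihood on the log scale over `[1e-6, 1e6]`). BLUPs of `b` and the
#' breeding values `a` are returned at the optimum. A non-PSD `K` is
#' ridge-repaired by `(|min eigenvalue| + 1e-8) I` with a message. Boundary
#' optima (heritability pinned near 0 or 1) are flagged, not errors.
#'
#' @param y numeric phenotype vector.
#' @param X fixed-effect design matrix (intercept + blocks, optionally
#'   structure covariates); linearly dependent columns are dropped.
#' @param K [KinshipMatrix-class] or symmetric matrix aligned with `y`.
#' @param tol relative tolerance of the 1-D likelihood search.
#' @return list (`VarianceComponents` + solutions): `sigma2_a`, `sigma2_e`,
#'   `sigma2_y`, `h2`, `se_h2`, `lambda`, `b_hat`, `a_hat`, `loglik`,
#'   `boundary`, `kept_cols`, and the reusable spectrum `eigenK`.
#' @export
remlFit <- function(y, X, K, tol = 1e-8) {
  Km <- if (is(K, "KinshipMatrix")) as.matrix(K) else K
  n <- length(y)
  stopifnot(nrow(Km) == n, nrow(X) == n)
  keep <- .independentCols(X)
  X <- X[, keep, drop = FALSE]
  q <- ncol(X)
  if (n < q + 2) stop("too few observations for the fixed-effect design")
  ee <- eigen(Km, symmetric = TRUE)
  if (min(ee$values) < -1e-8) {
    ridge <- abs(min(ee$values)) + 1e-8
    message(sprintf("remlFit: kinship not PSD, ridge %.3g added", ridge))
    ee$values <- ee$values + ridge
  }
  d <- pmax(ee$values, 0)
  U <- ee$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  restLik <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    XtWX <- crossprod(Xt, w * Xt)
    bh <- solve(XtWX, crossprod(Xt, w * yt))
    r <- yt - Xt %*% bh
    s2e <- sum(w * r^2) / (n - q)
    -0.5 * ((n - q) * log(s2e) + sum(log(lam * d + 1)) +
              determinant(XtWX, logarithm = TRUE)$modulus[1] + (n - q))
  }
  opt <- optimize(restLik, c(log(1e-6), log(1e6)), maximum = TRUE, tol = tol)
  loglam <- opt$maximum
  boundary <- loglam < log(1e-6) + 0.01 || loglam > log(1e6) - 0.01
  lam <- exp(loglam)
  w <- 1 / (lam * d + 1)
  XtWX <- crossprod(Xt, w * Xt)
  bh <- solve(XtWX, crossprod(Xt, w * yt))
  r <- yt - Xt %*% bh
  s2e <- sum(w * r^2) / (n - q)
  s2a <- lam * s2e
  ah <- drop(U %*% (lam * d * w * r))
  names(ah) <- rownames(Km)
  h2 <- s2a / (s2a + s2e)
  # curvature-based standard error of h2 via the profile in log-lambda
  eps <- 1e-3
  d2 <- (restLik(loglam + eps) - 2 * opt$objective + restLik(loglam - eps)) /
    eps^2
  seH2 <- if (is.finite(d2) && d2 < 0 && !boundary)
    (lam / (1 + lam)^2) / sqrt(-d2) else NA_real_
  list(sigma2_a = s2a, sigma2_e = s2e, sigma2_y = s2a + s2e, h2 = h2,
       se_h2 = seH2, lambda = lam, b_hat = drop(bh), a_hat = ah,
       loglik = opt$objective, boundary = boundary, kept_cols = keep,
       eigenK = list(U = U, d = d))
}

#' Ridge (RR-BLUP) marker effects from a kinship-route fit
#'
#' Backsolves per-marker effects from the GBLUP solution:
#' `m_hat = sigma2_m W' V^{-1} (y - X b_hat)` with `W` the dosage matrix
#' centered by twice the allele frequency, `sigma2_m = sigma2_a / (2 sum
#' p(1-p))` and `V = sigma2_a G + sigma2_e I`. When `G` was built from the
#' same centered markers, `W m_hat` reproduces the GBLUP breeding values
#' (the two routes are algebraically identical).
#'
#' @param y,X as in [remlFit()].
#' @param g [GenotypeData-class] (imputed) or complete dosage matrix -- the
#'   markers from which `G` was built.
#' @param fit a [remlFit()] result on the VanRaden `G` of `g`; fitted here
#'   when `NULL`.
#' @return list: `m_hat` (named marker effects), `gebv` (`W m_hat`),
#'   `allele_freq`, and the `fit` used.
#' @export
rrblupEffects <- function(y, X, g, fit = NULL) {
  M <- if (is(g, "GenotypeData")) dosages(imputeMean(g)) else g
  if (is.null(fit)) fit <- remlFit(y, X, grmVanRaden(M))
  pk <- colMeans(M) / 2
  denom <- 2 * sum(pk * (1 - pk))
  W <- sweep(M, 2, 2 * pk)
  U <- fit$eigenK$U; d <- fit$eigenK$d; lam <- fit$lambda
  Xk <- X[, fit$kept_cols, drop = FALSE]
  r <- y - Xk %*% fit$b_hat
  vinvR <- U %*% ((1 / (lam * d + 1)) * crossprod(U, r)) / fit$sigma2_e
  mh <- drop((fit$sigma2_a / denom) * crossprod(W, vinvR))
  names(mh) <- colnames(M)
  list(m_hat = mh, gebv = setNames(drop(W %*% mh), rownames(M)),
       allele_freq = pk, fit = fit)
}

#' Bayesian whole-genome regression by Gibbs sampling
#'
#' Samples the marker-effect model `y = X b + Z m + e` under one of five
#' priors on `m`: Bayesian ridge regression (`brr`), Bayes A (`bayes_a`),
#' Bayes B (`bayes_b`), Bayes C-pi (`bayes_c_pi`) or the Bayesian lasso
#' (`bl`). Fixed effects carry the flat prior `N(0, 1e6 I)` and the
#' residual variance a scaled inverse chi-square `(nu_e, S_e)`. Default
#' hyper-scales are solved so the prior mode assigns half the phenotypic
#' variance to markers; all are overridable. `fix_var = TRUE` freezes the
#' residual and (common) marker variances at supplied values -- the
#' conjugate setting whose posterior mean has a closed form, used for
#' sampler verification.
#'
#' @param y phenotype vector.
#' @param X fixed-effect design (intercept + blocks).
#' @param Z marker dosage matrix (complete; centered internally).
#' @param method one of `"brr"`, `"bayes_a"`, `"bayes_b"`, `"bayes_c_pi"`,
#'   `"bl"`.
#' @param n_iter,burn_in,thin MCMC schedule (defaults 200000 / 50000 / 5).
#' @param seed optional seed (drives R's RNG inside the sampler).
#' @param nu_e,S_e residual-variance prior df and scale.
#' @param nu_m,S_m marker-variance prior df and scale.
#' @param pi_incl prior/starting inclusion probability for Bayes B / C
#'   (Bayes B starts at 0.01, i.e. 99% of markers excluded).
#' @param update_pi Beta(1,1)-update the inclusion rate (default `TRUE`
#'   for Bayes B / C).
#' @param bl_shape,bl_rate Gamma prior on the lasso regularization
#'   `lambda^2`.
#' @param fix_var freeze variances (BRR only).
#' @param sigma_e2,sigma_m2 frozen values when `fix_var`.
#' @param center center marker columns (default `TRUE`).
#' @return list (`PosteriorSummary`): `m_hat` (posterior-mean effects),
#'   `b_hat`, `gebv` (`Z_c m_hat`), `h2_samples`, `h2_mean`, `hyper`
#'   (posterior means of the method's hyperparameters), `chain`.
#' @export
gibbsFit <- function(y, X, Z, method = c("brr", "bayes_a", "bayes_b",
                                         "bayes_c_pi", "bl"),
                     n_iter = 200000, burn_in = 50000, thin = 5,
                     seed = NULL, nu_e = 5, S_e = NULL, nu_m = 5,
                     S_m = NULL, pi_incl = NULL, update_pi = NULL,
                     bl_shape = 1.1, bl_rate = 1e-4, fix_var = FALSE,
                     sigma_e2 = NULL, sigma_m2 = NULL, center = TRUE) {
  method <- match.arg(method)
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if (!is.null(seed)) set.seed(seed)
  if (anyNA(Z)) stop("Z must be fully observed (mean-impute first)")
  keep <- .independentCols(X)
  X <- X[, keep, drop = FALSE]
  Zc <- if (center) scale(Z, center = TRUE, scale = FALSE) else Z
  vy <- var(y)
  R2 <- 0.5
  msx <- sum(apply(Zc, 2, var))
  if (is.null(S_e)) S_e <- vy * (1 - R2) * (nu_e + 2) / nu_e
  if (is.null(pi_incl)) pi_incl <- switch(method, bayes_b = 0.01,
                                          bayes_c_pi = 0.5, 0.5)
  if (is.null(update_pi)) update_pi <- method %in% c("bayes_b", "bayes_c_pi")
  if (is.null(S_m)) {
    S_m <- vy * R2 * (nu_m + 2) / nu_m / max(msx, 1e-12)
    if (method %in% c("bayes_b", "bayes_c_pi")) S_m <- S_m / pi_incl
  }
  code <- match(method, c("brr", "bayes_a", "bayes_b", "bayes_c_pi", "bl")) - 1L
  if (fix_var && method != "brr")
    stop("fix_var is supported for the BRR sampler only")
  res <- .gibbs_wgr_cpp(as.numeric(y), X, Zc, code, as.integer(n_iter),
                        as.integer(burn_in), as.integer(thin),
                        nu_e, S_e, nu_m, S_m, pi_incl, update_pi,
                        bl_shape, bl_rate, fix_var,
                        ifelse(is.null(sigma_e2), 0, sigma_e2),
                        ifelse(is.null(sigma_m2), 0, sigma_m2))
  mh <- drop(res$m_mean)
  names(mh) <- colnames(Z)
  hyper <- list(sigma_e2 = mean(res$s2e_samples),
                sigma_m2 = mean(res$s2m_samples))
  if (method %in% c("bayes_b", "bayes_c_pi"))
    hyper$pi <- mean(res$pi_samples)
  if (method == "bl") hyper$lambda2 <- mean(res$lambda2_samples)
  list(m_hat = mh, b_hat = drop(res$b_mean),
       gebv = setNames(drop(Zc %*% mh), rownames(Z)),
       h2_samples = res$h2_samples, h2_mean = mean(res$h2_samples),
       hyper = hyper,
       chain = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                    n_saved = res$n_saved, seed = seed, method = method,
                    kept_cols = keep))
}

#' Predictive ability
#'
#' Pearson correlation between observed phenotypes and (genomic) estimated
#' breeding values of the same individuals.
#'
#' @param y_obs,gebv aligned numeric vectors, length >= 3.
#' @return scalar correlation.
#' @export
predictiveAbility <- function(y_obs, gebv) {
  if (length(y_obs) != length(gebv)) stop("vectors must be aligned")
  if (length(y_obs) < 3) stop("need at least 3 pairs")
  if (sd(y_obs) == 0 || sd(gebv) == 0) stop("zero variance input")
  cor(y_obs, gebv)
}

#' K-fold cross-validated genomic prediction
#'
#' Random (stratification-free) partition into `k_folds` folds; each fold
#' in turn is the validation set, the model is trained on the rest, and
#' validation breeding values are predicted -- by kinship projection
#' (`ablup`/`gblup`: `lambda K_vt (lambda K_tt + I)^{-1} r_t`) or from
#' marker effects (`rrblup` and the Bayesian methods: `W_v m_hat`, with
#' validation dosages centered at training allele frequencies). Fold
#' predictive ability is the correlation between validation phenotypes
#' (block effects estimated on training data removed, toggleable) and the
#' predicted breeding values.
#'
#' @param y phenotype vector (names or order aligned with genotypes).
#' @param X fixed-effect design for the full data (intercept + blocks).
#' @param g [GenotypeData-class] (marker routes and `gblup`).
#' @param K [KinshipMatrix-class] (kinship routes; built from `g` as
#'   VanRaden when `NULL` and `method` is `gblup`).
#' @param method `"ablup"`, `"gblup"`, `"rrblup"`, `"brr"`, `"bayes_a"`,
#'   `"bayes_b"`, `"bayes_c_pi"`, `"bl"`.
#' @param k_folds number of folds (>= 2).
#' @param seed optional seed (fold assignment + samplers).
#' @param chain list of MCMC schedule overrides for Bayesian methods.
#' @param adjust_validation remove training-estimated fixed effects from
#'   validation phenotypes before correlating (default `TRUE`).
#' @return list (`CVResult`): `fold_r`, `mean_r`, `se_r`,
#'   `fold_assignments`, `gebv` (out-of-fold predictions), `method`.
#' @export
crossValidate <- function(y, X, g = NULL, K = NULL,
                          method = "gblup", k_folds = 10, seed = NULL,
                          chain = list(), adjust_validation = TRUE) {
  if (k_folds < 2) stop("k_folds must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  markerRoute <- method %in% c("rrblup", "brr", "bayes_a", "bayes_b",
                               "bayes_c_pi", "bl")
  if (markerRoute && is.null(g)) stop("marker-route methods need genotypes")
  if (!markerRoute && is.null(K)) {
    if (method == "gblup" && !is.null(g)) K <- grmVanRaden(imputeMean(g))
    else stop("kinship-route methods need K")
  }
  M <- if (!is.null(g)) dosages(imputeMean(g)) else NULL
  Km <- if (!is.null(K)) as.matrix(K) else NULL
  folds <- sample(rep(seq_len(k_folds), length.out = n))
  gebv <- rep(NA_real_, n)
  foldR <- numeric(k_folds)
  ch <- utils::modifyList(list(n_iter = 200000, burn_in = 50000, thin = 5),
                          chain)
  for (f in seq_len(k_folds)) {
    v <- which(folds == f)
    t <- which(folds != f)
    if (length(v) < 3) stop("fold with fewer than 3 validation individuals")
    Xt <- X[t, , drop = FALSE]
    if (markerRoute) {
      Mt <- M[t, , drop = FALSE]
      pk <- colMeans(Mt) / 2
      Wt <- sweep(Mt, 2, 2 * pk)
      Wv <- sweep(M[v, , drop = FALSE], 2, 2 * pk)
      if (method == "rrblup") {
        fit <- remlFit(y[t], Xt, grmVanRaden(Mt))
        eff <- rrblupEffects(y[t], Xt, Mt, fit = fit)
        mh <- eff$m_hat
        bcols <- fit$kept_cols
        bhat <- fit$b_hat
      } else {
        fit <- gibbsFit(y[t], Xt, Mt, method = method, n_iter = ch$n_iter,
                        burn_in = ch$burn_in, thin = ch$thin)
        mh <- fit$m_hat
        bcols <- fit$chain$kept_cols
        bhat <- fit$b_hat
      }
      pred <- drop(Wv %*% mh)
    } else {
      fit <- remlFit(y[t], Xt, Km[t, t])
      bcols <- fit$kept_cols
      bhat <- fit$b_hat
      r <- y[t] - Xt[, bcols, drop = FALSE] %*% bhat
      lam <- fit$lambda
      sol <- solve(lam * Km[t, t] + diag(length(t)), r)
      pred <- drop(lam * Km[v, t, drop = FALSE] %*% sol)
    }
    yv <- y[v]
    if (adjust_validation)
      yv <- yv - drop(X[v, bcols, drop = FALSE] %*% bhat)
    foldR[f] <- if (sd(pred) == 0 || sd(yv) == 0) 0 else cor(yv, pred)
    gebv[v] <- pred
  }
  list(fold_r = foldR, mean_r = mean(foldR),
       se_r = sd(foldR) / sqrt(k_folds), fold_assignments = folds,
       gebv = setNames(gebv, names(y)), method = method)
}

#' Write a CV result as JSON + per-fold TSV
#' @param cv result of [crossValidate()]
#' @param prefix output path prefix (`prefix.json`, `prefix_folds.tsv`)
#' @export
writeCvResult <- function(cv, prefix) {
  jsonlite::write_json(cv[c("fold_r", "mean_r", "se_r", "method")],
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write.table(data.frame(fold = seq_along(cv$fold_r), r = cv$fold_r),
              paste0(prefix, "_folds.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}
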