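test_that("REML with identity kinship reduces to ordinary least squares", {
  set.seed(3)
  n <- 120
  block <- rep(1:6, each = 20)
  X <- treegs:::.blockDesign(block)
  y <- drop(X %*% c(5, rnorm(5, 0, 0.5))) + rnorm(n)
  I <- diag(n)
  dimnames(I) <- list(paste0("s", 1:n), paste0("s", 1:n))
  fit <- remlFit(y, X, I)
  ols <- lm(y ~ factor(block))
  # with K = I the likelihood is flat in the split between sigma2_a and
  # sigma2_e; fixed effects and total variance are still identified
  expect_equal(unname(fit$b_hat), unname(coef(ols)), tolerance = 1e-4)
  expect_equal(fit$sigma2_y, summary(ols)$sigma^2, tolerance = 1e-3)
})

test_that("null and boundary heritabilities are recovered and flagged", {
  st <- smallStudy()
  g <- suppressMessages(filterSnps(st$geno))
  G <- grmVanRaden(imputeMean(g))
  X <- blockX(st)
  c0 <- st$cfg; c0$h2_true <- 0
  tr0 <- simulateTrait(st$complete, st$pedigree, c0, seed = 55)
  fit0 <- remlFit(tr0$phen$trait, X, G)
  expect_lt(fit0$h2, 0.05)
  expect_true(fit0$boundary)
})

test_that("GBLUP and RR-BLUP breeding values coincide and marker effects obey oracles", {
  st <- smallStudy()
  gi <- imputeMean(suppressMessages(filterSnps(st$geno)))
  y <- st$phen$trait
  X <- blockX(st)
  fit <- remlFit(y, X, grmVanRaden(gi))
  eff <- rrblupEffects(y, X, gi, fit = fit)
  expect_lt(max(abs(eff$gebv - fit$a_hat)), 1e-6 * sd(y))
  # independent direct-solve oracle for the marker effects on a small panel
  sub <- gi[1:40, 1:25]
  M <- dosages(sub)
  keep <- apply(M, 2, var) > 0
  M <- M[, keep, drop = FALSE]
  ys <- y[1:40]
  Xs <- matrix(1, 40, 1)
  G <- grmVanRaden(M)
  fs <- remlFit(ys, Xs, G)
  pk <- colMeans(M) / 2
  W <- sweep(M, 2, 2 * pk)
  denom <- 2 * sum(pk * (1 - pk))
  V <- fs$sigma2_a * as.matrix(G) + fs$sigma2_e * diag(40)
  mOracle <- drop((fs$sigma2_a / denom) * crossprod(W, solve(V, ys - fs$b_hat)))
  eff2 <- rrblupEffects(ys, Xs, M, fit = fs)
  expect_equal(unname(eff2$m_hat), unname(mOracle), tolerance = 1e-8)
  # a monomorphic (zero after centering) marker receives a zero effect
  M2 <- cbind(M, fixed = 2)
  eff3 <- rrblupEffects(ys, Xs, M2, fit = NULL)
  expect_equal(unname(eff3$m_hat["fixed"]), 0)
})

test_that("the Gibbs engine reproduces the conjugate ridge posterior", {
  set.seed(11)
  n <- 120; p <- 50
  Z <- matrix(rbinom(n * p, 2, 0.4), n, p,
              dimnames = list(paste0("i", 1:n), paste0("m", 1:p)))
  X <- matrix(1, n, 1)
  y <- drop(scale(Z, scale = FALSE) %*% rnorm(p, 0, 0.1)) + rnorm(n)
  s2e <- 1; s2m <- 0.01
  Zc <- scale(Z, scale = FALSE)
  C <- cbind(X, Zc)
  Prec <- crossprod(C) / s2e + diag(c(1e-6, rep(1 / s2m, p)))
  postMean <- drop(solve(Prec, crossprod(C, y) / s2e))
  postSd <- sqrt(diag(solve(Prec)))[-1]
  fit <- gibbsFit(y, X, Z, method = "brr", n_iter = 6000, burn_in = 1000,
                  thin = 1, seed = 1, fix_var = TRUE, sigma_e2 = s2e,
                  sigma_m2 = s2m)
  mcse <- postSd * sqrt(5 / fit$chain$n_saved)  # autocorrelation allowance
  expect_true(all(abs(fit$m_hat - postMean[-1]) < 3 * mcse + 1e-8))
})

test_that("posterior heritability concentrates near zero for a null trait", {
  # needs a trial-sized sample: with few hundred individuals the marker
  # term is weakly identified and the posterior cannot collapse
  cfg <- simConfig(ne = 35, n_chrom = 11, chrom_len_bp = 5e7,
                   n_markers = 5000, n_families = 24,
                   progeny_per_family = 31, h2_true = 0, n_qtl = 300,
                   seed = 500)
  st <- simulateStudy(cfg)
  gi <- imputeMean(suppressMessages(filterSnps(st$geno)))
  X <- blockX(st)
  h2s <- vapply(1:3, function(s) {
    tr0 <- simulateTrait(st$complete, st$pedigree, cfg, seed = 900 + s)
    gibbsFit(tr0$phen$trait, X, dosages(gi), method = "brr",
             n_iter = 2000, burn_in = 700, thin = 2, seed = s)$h2_mean
  }, numeric(1))
  expect_lt(median(h2s), 0.1)
})

test_that("Bayes B localizes signal on sparse architectures", {
  st <- smallStudy()
  gi <- imputeMean(suppressMessages(filterSnps(st$geno)))
  cfgQ <- st$cfg; cfgQ$n_qtl <- 20; cfgQ$h2_true <- 0.5
  tr <- simulateTrait(st$complete, st$pedigree, cfgQ, seed = 66)
  fit <- gibbsFit(tr$phen$trait, blockX(st), dosages(gi),
                  method = "bayes_b", n_iter = 3000, burn_in = 1000,
                  thin = 2, seed = 4)
  isQtl <- names(fit$m_hat) %in% tr$truth$qtl_markers
  expect_gt(sum(isQtl), 10)  # most QTL survive QC
  wt <- wilcox.test(abs(fit$m_hat[isQtl]), abs(fit$m_hat[!isQtl]),
                    alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("all five Bayesian samplers run, mix and agree with REML broadly", {
  st <- smallStudy()
  gi <- imputeMean(suppressMessages(filterSnps(st$geno)))
  y <- st$phen$trait
  X <- blockX(st)
  reml <- remlFit(y, X, grmVanRaden(gi))
  h2s <- vapply(c("brr", "bayes_a", "bayes_b", "bayes_c_pi", "bl"),
                function(m) {
                  f <- gibbsFit(y, X, dosages(gi), method = m,
                                n_iter = 2500, burn_in = 1000, thin = 2,
                                seed = 8)
                  expect_equal(f$chain$n_saved, 750)
                  f$h2_mean
                }, numeric(1))
  expect_true(all(h2s > 0 & h2s < 1))
  expect_lt(max(abs(h2s - reml$h2)), 0.2)
  expect_error(gibbsFit(y, X, dosages(gi), n_iter = 100, burn_in = 200),
               "exceed")
})

test_that("predictive ability is a guarded Pearson correlation", {
  expect_equal(predictiveAbility(1:5, 1:5), 1)
  expect_equal(predictiveAbility(1:5, 5:1), -1)
  y <- c(1.2, 0.7, 2.5, 1.9, 0.3)
  g <- c(0.8, 0.2, 1.9, 2.2, 0.7)
  expect_equal(predictiveAbility(y, g), cor(y, g))
  expect_error(predictiveAbility(1:2, 1:2), "3 pairs")
  expect_error(predictiveAbility(1:4, rep(1, 4)), "zero variance")
  expect_error(predictiveAbility(1:4, 1:3), "aligned")
})

test_that("cross-validation partitions cleanly and is seed-reproducible", {
  st <- smallStudy()
  g <- suppressMessages(filterSnps(st$geno))
  y <- st$phen$trait
  names(y) <- st$phen$id
  X <- blockX(st)
  cv <- crossValidate(y, X, g = g, method = "gblup", k_folds = 5, seed = 9)
  expect_length(cv$fold_r, 5)
  expect_true(all(abs(cv$fold_r) <= 1))
  expect_equal(sort(unique(cv$fold_assignments)), 1:5)
  expect_false(anyNA(cv$gebv))
  cv2 <- crossValidate(y, X, g = g, method = "gblup", k_folds = 5, seed = 9)
  expect_identical(cv$fold_r, cv2$fold_r)
  expect_gt(cv$mean_r, 0.15)  # heritable trait must be predictable
  expect_error(crossValidate(y, X, g = g, k_folds = 1), "at least 2")
  expect_error(crossValidate(y, X, method = "brr"), "need genotypes")
})

test_that("rare-allele exclusion barely moves predictive ability", {
  st <- smallStudy()
  g0 <- suppressMessages(filterSnps(st$geno, maf_min = 0))
  g5 <- suppressMessages(filterSnps(st$geno, maf_min = 0.05))
  expect_lt(nMarkers(g5), nMarkers(g0))  # strict shrinkage of the panel
  y <- st$phen$trait
  X <- blockX(st)
  r0 <- crossValidate(y, X, g = g0, method = "gblup", k_folds = 5,
                      seed = 14)$mean_r
  r5 <- crossValidate(y, X, g = g5, method = "gblup", k_folds = 5,
                      seed = 14)$mean_r
  expect_lt(abs(r0 - r5), 0.02)
})

test_that("single-chromosome panels capture less heritability than all SNPs", {
  st <- smallStudy()
  gi <- imputeMean(suppressMessages(filterSnps(st$geno)))
  y <- st$phen$trait
  X <- blockX(st)
  h2All <- remlFit(y, X, grmVanRaden(gi))$h2
  h2Chr <- vapply(unique(gi@map$chrom), function(ch) {
    remlFit(y, X, grmVanRaden(gi[, gi@map$chrom == ch]))$h2
  }, numeric(1))
  expect_true(all(h2Chr < h2All))
})
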