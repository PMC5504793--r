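test_that("config validation rejects impossible designs", {
  expect_error(simConfig(ne = 1), "ne")
  expect_error(simConfig(fst = 1))
  expect_error(simConfig(h2_true = 1.2))
  expect_error(simConfig(n_qtl = 100, n_markers = 50))
  expect_error(simConfig(n_markers = 100, n_chrom = 1, chrom_len_bp = 10,
                         n_qtl = 10), "distinguishable")
  expect_equal(simConfig(ne = 20)$equil_gens, 80)
})

test_that("zero drift generations return the initialization draw", {
  cfg <- simConfig(ne = 2, n_chrom = 1, chrom_len_bp = 1e6, n_markers = 10,
                   n_families = 2, progeny_per_family = 2, equil_gens = 0,
                   n_qtl = 2, seed = 5)
  pool <- simulateBasePool(cfg, seed = 5)
  # reproduce the draw: map consumes RNG first, then f0, then the gamete pool
  set.seed(5)
  map <- treegs:::.simMap(cfg)
  f0 <- runif(10)
  H <- matrix(rbinom(2 * 2 * 10, 1, rep(f0, each = 4)), nrow = 4)
  expect_equal(pool$H[[1]], H)
  expect_equal(pool$init_freq, f0)
})

test_that("island divergence hits the Hudson-Fst target", {
  fsts <- vapply(1:10, function(s) {
    cfg <- simConfig(ne = 50, n_chrom = 2, chrom_len_bp = 1e7,
                     n_markers = 400, n_families = 4,
                     progeny_per_family = 2, fst = 0.1, equil_gens = 60,
                     seed = s)
    pool <- simulateBasePool(cfg, seed = s)
    hudsonFst(pool$H[[1]], pool$H[[2]])
  }, numeric(1))
  expect_gt(mean(fsts), 0.05)
  expect_lt(mean(fsts), 0.15)
})

test_that("open-pollinated families are half-sib structured", {
  st <- smallStudy()
  A <- as.matrix(pedigreeA(st$pedigree))
  fam <- st$pedigree$mother
  same <- outer(fam, fam, "==")
  up <- upper.tri(A)
  expect_true(all(A[same & up] == 0.25))
  expect_true(all(A[!same & up] == 0))
  expect_true(all(diag(A) == 1))
  # realized genomic relationship within families near the half-sib 0.25
  inFam <- vapply(1:3, function(s) {
    cfg <- simConfig(ne = 35, n_chrom = 3, chrom_len_bp = 2e7,
                     n_markers = 4000, n_families = 24,
                     progeny_per_family = 8, n_qtl = 20, seed = 400 + s)
    stx <- simulateStudy(cfg)
    G <- as.matrix(grmVanRaden(imputeMean(filterSnps(stx$geno))))
    sm <- outer(stx$pedigree$mother, stx$pedigree$mother, "==") &
      upper.tri(G)
    mean(G[sm])
  }, numeric(1))
  expect_lt(abs(mean(inFam) - 0.25), 0.05)
})

test_that("single-progeny families give a diagonal pedigree A", {
  cfg <- simConfig(ne = 20, n_chrom = 1, chrom_len_bp = 1e6,
                   n_markers = 50, n_families = 10, progeny_per_family = 1,
                   n_qtl = 5, seed = 2)
  st <- simulateStudy(cfg)
  A <- as.matrix(pedigreeA(st$pedigree))
  expect_equal(A, diag(10), ignore_attr = TRUE)
})

test_that("family demand beyond the pool is an error", {
  cfg <- simConfig(ne = 5, n_chrom = 1, chrom_len_bp = 1e6, n_markers = 20,
                   n_families = 8, progeny_per_family = 2, n_qtl = 2,
                   equil_gens = 5, seed = 1)
  pool <- simulateBasePool(cfg, seed = 1)
  expect_error(sampleOpFamilies(pool, cfg), "demand exceeds")
})

test_that("trait construction honors the generative model", {
  st <- smallStudy()
  cfg <- st$cfg
  # noise-free, block-free trait equals the breeding values exactly
  c1 <- cfg; c1$h2_true <- 1; c1$block_sd <- 0
  tr <- simulateTrait(st$complete, st$pedigree, c1, seed = 9)
  expect_equal(tr$phen$trait - 10, unname(tr$truth$bv), tolerance = 1e-12)
  expect_equal(tr$truth$realized_h2, 1)
  # null trait: breeding values essentially uncorrelated with phenotype
  c0 <- cfg; c0$h2_true <- 0
  tr0 <- simulateTrait(st$complete, st$pedigree, c0, seed = 9)
  expect_lt(abs(cor(tr0$truth$bv, tr0$phen$trait)), 0.1)
  expect_lt(tr0$truth$realized_h2, 1e-4)
  expect_gt(var(tr0$truth$bv), 0)  # effects not nulled, residual inflated
  # realized heritability tracks the target at n >= 500
  cfgBig <- simConfig(ne = 30, n_chrom = 2, chrom_len_bp = 2e7,
                      n_markers = 3000, n_families = 25,
                      progeny_per_family = 21, h2_true = 0.3, n_qtl = 60,
                      seed = 77)
  stBig <- simulateStudy(cfgBig)
  expect_lt(abs(stBig$truth$realized_h2 - 0.3), 0.1)
  # block layout: one tree per family per block while capacity lasts
  tab <- table(st$phen$family, st$phen$block)
  expect_true(all(tab <= 1))
  expect_error(simulateTrait(st$complete, st$pedigree,
                             within.list(cfg, {n_qtl <- 0; h2_true <- 0.3})),
               "degenerate")
})

test_that("gene annotation covers the target fraction and classifies markers", {
  st <- smallStudy()
  genes <- annotateGenes(st$map, genic_fraction = 0.5,
                         chrom_len_bp = st$cfg$chrom_len_bp, seed = 4)
  cov <- sum(GenomicRanges::width(genes)) /
    (st$cfg$n_chrom * st$cfg$chrom_len_bp)
  expect_lt(abs(cov - 0.5) / 0.5, 0.10)
  mask <- genicMask(st$map, genes)
  expect_length(mask, nrow(st$map))
  # brute-force interval membership on one chromosome
  one <- st$map$chrom == "chr01"
  gr1 <- genes[GenomicRanges::seqnames(genes) == "chr01"]
  bf <- vapply(st$map$pos_bp[one], function(p)
    any(p >= GenomicRanges::start(gr1) & p <= GenomicRanges::end(gr1)),
    logical(1))
  expect_equal(mask[one], bf)
  # genic and intergenic counts roughly balance at fraction 0.5
  expect_lt(abs(sum(mask) - sum(!mask)) / length(mask), 0.2)
  expect_error(annotateGenes(st$map, genic_fraction = 1), "fraction")
  # BED round trip
  path <- tempfile(fileext = ".bed")
  writeGenesBed(genes, path)
  back <- rtracklayer::import(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(genes))
})

test_that("phased pool and dosage coding are consistent", {
  st <- smallStudy()
  stopifnot(any(is.na(dosages(st$geno))))
  obs <- dosages(st$geno)
  expect_true(all(obs[!is.na(obs)] %in% 0:2))
  expect_true(all(st$complete %in% 0:2))
  # observed entries agree with the pre-missingness truth
  expect_true(all(obs[!is.na(obs)] ==
                    st$complete[!is.na(obs)]))
})

test_that("identical seed gives a bit-identical study", {
  cfg <- simConfig(ne = 20, n_chrom = 2, chrom_len_bp = 5e6,
                   n_markers = 400, n_families = 8, progeny_per_family = 6,
                   n_qtl = 20, seed = 31)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(dosages(a$geno), dosages(b$geno))
  expect_identical(a$phen, b$phen)
  expect_identical(a$truth, b$truth)
})
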