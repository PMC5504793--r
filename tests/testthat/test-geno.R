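test_that("call-rate and MAF filters apply the printed boundary semantics", {
  g <- toyGeno()
  # m3 monomorphic; m4 (4/6) and m5 (5/6) miss the 90% call-rate bar
  kept <- suppressMessages(filterSnps(g, cr_min = 0.9, maf_min = 0))
  expect_equal(markerIds(kept), c("m1", "m2"))
  # cr_min = 0 keeps the low-call-rate markers; MAF > 0 still drops m3
  kept2 <- suppressMessages(filterSnps(g, cr_min = 0, maf_min = 0))
  expect_equal(markerIds(kept2), c("m1", "m2", "m4", "m5"))
  # identity on clean polymorphic data
  clean <- g[, c("m1", "m2")]
  expect_equal(markerIds(suppressMessages(filterSnps(clean, 0, 0))),
               c("m1", "m2"))
  # maf_min > 0 is inclusive at the boundary
  d <- cbind(a = c(1, rep(0, 9)), b = c(2, 2, rep(0, 8)))
  rownames(d) <- paste0("s", 1:10)
  gb <- GenotypeData(d, data.frame(marker = c("a", "b"), chrom = "c1",
                                   pos_bp = c(1, 2)))
  # a: maf 0.05 exactly (kept); b: maf 0.2
  keptB <- suppressMessages(filterSnps(gb, cr_min = 0, maf_min = 0.05))
  expect_equal(markerIds(keptB), c("a", "b"))
  expect_error(suppressMessages(filterSnps(gb, cr_min = 0, maf_min = 0.5)),
               "no markers")
})

test_that("filters are idempotent and leave the input untouched", {
  g <- smallStudy()$geno
  before <- dosages(g)
  f1 <- suppressMessages(filterSnps(g))
  f2 <- suppressMessages(filterSnps(f1))
  expect_identical(markerIds(f1), markerIds(f2))
  expect_identical(dosages(g), before)
})

test_that("mean imputation fills missing calls with the marker mean", {
  g <- toyGeno()[, c("m1", "m5")]
  gi <- imputeMean(g)
  # m5 observed {0,2,0,1,2} -> mean 1.0 into i3
  expect_equal(dosages(gi)["i3", "m5"], 1.0)
  expect_equal(dosages(gi)[-3, "m5"], dosages(g)[-3, "m5"])
  # no-missing input is returned unchanged
  full <- toyGeno()[, "m1"]
  expect_identical(dosages(imputeMean(full)), dosages(full))
  # column means preserved to 1e-12 under random missingness
  st <- smallStudy()
  gg <- suppressMessages(filterSnps(st$geno))
  gi2 <- imputeMean(gg)
  expect_lt(max(abs(colMeans(dosages(gi2)) -
                      colMeans(dosages(gg), na.rm = TRUE))), 1e-12)
  # all-missing marker is an error pointing at filtering
  d <- cbind(a = c(NA, NA), b = c(0, 1))
  rownames(d) <- c("x", "y")
  bad <- GenotypeData(d, data.frame(marker = c("a", "b"), chrom = "c1",
                                    pos_bp = 1:2))
  expect_error(imputeMean(bad), "filter")
})

test_that("LD pruning removes duplicates and leaves equilibrium sets alone", {
  set.seed(8)
  base <- rbinom(40, 2, 0.4)
  d <- cbind(a = base, b = base, c = rbinom(40, 2, 0.5))
  rownames(d) <- paste0("s", 1:40)
  g <- GenotypeData(d, data.frame(marker = c("a", "b", "c"), chrom = "c1",
                                  pos_bp = c(1000, 2000, 3000)))
  kept <- ldPrune(g, window_kb = 100, r2_max = 0.2)
  expect_length(setdiff(c("a", "b"), kept), 1)  # exactly one duplicate gone
  # independent markers all survive
  set.seed(9)
  d2 <- sapply(1:10, function(i) rbinom(500, 2, 0.5))
  colnames(d2) <- paste0("m", 1:10)
  rownames(d2) <- paste0("s", 1:500)
  g2 <- GenotypeData(d2, data.frame(marker = colnames(d2), chrom = "c1",
                                    pos_bp = seq(1e3, 1e4, length.out = 10)))
  expect_length(ldPrune(g2), 10)
  expect_error(ldPrune(g2, window_kb = 0), "positive")
})

test_that("pruning satisfies the post-hoc window oracle and is deterministic", {
  st <- smallStudy()
  g <- suppressMessages(filterSnps(st$geno))
  one <- g[, which(g@map$chrom == "chr01")[1:50]]
  kept <- ldPrune(one, window_kb = 100, r2_max = 0.2)
  expect_identical(kept, ldPrune(one, window_kb = 100, r2_max = 0.2))
  # brute-force recheck: no surviving within-window pair above 0.2
  M <- dosages(imputeMean(one))[, kept, drop = FALSE]
  pos <- one@map$pos_bp[match(kept, one@map$marker)]
  cc <- cor(M)^2
  for (i in seq_along(kept))
    for (j in seq_along(kept))
      if (j > i && pos[j] - pos[i] <= 1e5)
        expect_lte(cc[i, j], 0.2 + 1e-12)
})

test_that("the cumulative ladder is nested and chromosome-stratified", {
  st <- smallStudy()
  g <- suppressMessages(filterSnps(st$geno))
  lad <- sampleSubset(g, "random_stratified_cumulative",
                      sizes = c(60, 120, 300), seed = 3)
  expect_named(lad, c("60", "120", "300"))
  expect_true(all(lad[["60"]] %in% lad[["120"]]))
  expect_true(all(lad[["120"]] %in% lad[["300"]]))
  # proportional allocation per chromosome within +-2
  mm <- markerMap(g)
  tab <- table(factor(mm$chrom[match(lad[["120"]], mm$marker)],
                      levels = unique(mm$chrom)))
  expected <- 120 * table(factor(mm$chrom, levels = unique(mm$chrom))) /
    nrow(mm)
  expect_true(all(abs(as.numeric(tab) - as.numeric(expected)) <= 2))
  expect_error(sampleSubset(g, "random_noncumulative",
                            size = nMarkers(g) + 1), "exceeds")
})

test_that("evenly spaced subsets take one SNP per window, near its midpoint", {
  st <- smallStudy()
  g <- suppressMessages(filterSnps(st$geno))
  for (w in c(5e5, 1e6)) {
    ids <- sampleSubset(g, "evenly_spaced", window_bp = w)
    mm <- markerMap(g)
    sel <- mm[match(ids, mm$marker), ]
    win <- paste(sel$chrom, (sel$pos_bp - 1) %/% w)
    expect_false(any(duplicated(win)))
    # midpoint rule: chosen SNP no farther from the midpoint than any other
    all_w <- paste(mm$chrom, (mm$pos_bp - 1) %/% w)
    mid <- ((mm$pos_bp - 1) %/% w) * w + w / 2
    off <- abs(mm$pos_bp - mid)
    best <- tapply(off, all_w, min)
    expect_equal(as.numeric(best[win]),
                 as.numeric(off[match(ids, mm$marker)]))
  }
})

test_that("genic and intergenic subsets partition the panel", {
  st <- smallStudy()
  g <- suppressMessages(filterSnps(st$geno))
  genic <- sampleSubset(g, "genic", annotation = st$genes)
  inter <- sampleSubset(g, "intergenic", annotation = st$genes)
  expect_length(intersect(genic, inter), 0)
  expect_setequal(c(genic, inter), markerIds(g))
  expect_error(sampleSubset(g, "genic"), "annotation")
  chr2 <- sampleSubset(g, "single_chromosome", chrom = "chr02")
  expect_setequal(chr2, markerIds(g)[g@map$chrom == "chr02"])
  expect_error(sampleSubset(g, "single_chromosome", chrom = "chrXX"),
               "unknown")
})
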