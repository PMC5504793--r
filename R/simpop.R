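#' Configuration for the breeding-population simulator
#'
#' Bundles and validates every knob of the synthetic study generator. The
#' defaults emulate a tropical eucalypt open-pollinated progeny trial:
#' a small drift-effective base population (Ne around 35-50), 11
#' chromosomes, half-sib families measured in a randomized complete block
#' design, and an additive growth trait of moderate heritability.
#'
#' @param ne target effective population size per subpopulation (diploid
#'   individuals), `>= 2`.
#' @param n_chrom number of chromosomes.
#' @param chrom_len_bp physical length of each chromosome (bp).
#' @param n_markers total number of candidate biallelic sites; sites may
#'   drift to fixation, so the polymorphic count after QC is lower.
#' @param n_families number of open-pollinated maternal families.
#' @param progeny_per_family offspring genotyped per mother.
#' @param fst target divergence between two subpopulations; 0 disables
#'   structure. Divergence is accumulated by drifting two islands for
#'   `round(2 * ne * fst)` generations after the split.
#' @param n_qtl causal loci for the simulated trait.
#' @param h2_true simulated narrow-sense heritability in `[0, 1]`.
#' @param n_blocks blocks of the randomized complete block design.
#' @param block_sd standard deviation of block effects (trait units).
#' @param missing_rate per-genotype missing-call probability.
#' @param cm_per_mbp uniform recombination rate (centimorgan per megabase).
#' @param equil_gens generations of drift before sampling; default
#'   `4 * ne` lets linked LD equilibrate.
#' @param genic_fraction fraction of each chromosome covered by synthetic
#'   gene models.
#' @param seed RNG seed used by [simulateStudy()].
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(ne = 35, n_chrom = 11, chrom_len_bp = 50e6,
                      n_markers = 5500, n_families = 24,
                      progeny_per_family = 32, fst = 0, n_qtl = 300,
                      h2_true = 0.4, n_blocks = 40, block_sd = 0.25,
                      missing_rate = 0.01, cm_per_mbp = 1,
                      equil_gens = NULL, genic_fraction = 0.5, seed = 1L) {
  cfg <- list(ne = ne, n_chrom = n_chrom, chrom_len_bp = chrom_len_bp,
              n_markers = n_markers, n_families = n_families,
              progeny_per_family = progeny_per_family, fst = fst,
              n_qtl = n_qtl, h2_true = h2_true, n_blocks = n_blocks,
              block_sd = block_sd, missing_rate = missing_rate,
              cm_per_mbp = cm_per_mbp,
              equil_gens = if (is.null(equil_gens)) 4L * ne else equil_gens,
              genic_fraction = genic_fraction, seed = seed)
  stopifnot(ne >= 2, n_chrom >= 1, chrom_len_bp > 0, n_markers >= 1,
            n_families >= 1, progeny_per_family >= 1,
            fst >= 0, fst < 1, h2_true >= 0, h2_true <= 1,
            n_qtl <= n_markers, n_qtl >= 0, n_blocks >= 1, block_sd >= 0,
            missing_rate >= 0, missing_rate < 1, cm_per_mbp > 0,
            cfg$equil_gens >= 0, genic_fraction > 0, genic_fraction < 1)
  if (n_markers > n_chrom * chrom_len_bp)
    stop("marker count exceeds distinguishable sites")
  class(cfg) <- "SimConfig"
  cfg
}

# Marker map: sites spread as evenly as the per-chromosome allocation
# allows, positions drawn uniformly without replacement then sorted.
.simMap <- function(cfg) {
  per <- diff(round(seq(0, cfg$n_markers, length.out = cfg$n_chrom + 1)))
  chrom <- rep(sprintf("chr%02d", seq_len(cfg$n_chrom)), per)
  pos <- unlist(lapply(per, function(k)
    sort(sample.int(cfg$chrom_len_bp, k))), use.names = FALSE)
  data.frame(marker = sprintf("snp%05d", seq_len(cfg$n_markers)),
             chrom = chrom, pos_bp = pos, stringsAsFactors = FALSE)
}

# cumulative end column per chromosome block of a (map-ordered) label vector
.chromEnds <- function(chrom) cumsum(rle(chrom)$lengths)

# One Wright-Fisher generation: N diploids, each formed from two gametes of
# parents drawn uniformly with replacement (random mating, selfing allowed).
# Gamete recombination runs in compiled code.
.wfGeneration <- function(H, chrom, pos, morganPerChrom, lenBp) {
  N <- nrow(H) %/% 2L
  ends <- .chromEnds(chrom)
  .wf_gametes_cpp(H, sample.int(N, 2L * N, replace = TRUE), ends, pos,
                  rep(morganPerChrom, length(ends)), lenBp)
}

# Drift a pool for `gens` generations. Sites fixed in the pool can never
# re-segregate (no mutation), so they are periodically dropped from the
# active set and reconstituted as constant columns at the end -- an exact
# shortcut that leaves the distribution of every site untouched.
.driftPool <- function(H, gens, map, morganPerChrom, lenBp,
                       checkEvery = 5L) {
  if (gens == 0L) return(H)
  p <- ncol(H)
  nh <- nrow(H)
  act <- seq_len(p)
  fixedVal <- rep(NA_integer_, p)
  Ha <- H
  for (gen in seq_len(gens)) {
    Ha <- .wfGeneration(Ha, map$chrom[act], map$pos_bp[act], morganPerChrom,
                        lenBp)
    if (gen %% checkEvery == 0L || gen == gens) {
      cs <- colSums(Ha)
      seg <- cs > 0L & cs < nh
      if (!all(seg)) {
        fixedVal[act[!seg]] <- as.integer(cs[!seg] > 0L)
        act <- act[seg]
        Ha <- Ha[, seg, drop = FALSE]
      }
    }
  }
  out <- matrix(rep(fixedVal, each = nh), nh, p)
  out[, act] <- Ha
  out
}

#' Simulate the base haplotype pool by forward Wright-Fisher drift
#'
#' Runs a discrete-generation forward simulation of `ne` random-mating
#' diploids per subpopulation under a uniform recombination map. Sites start
#' at uniform-random allele frequencies and drift for `equil_gens`
#' generations (default `4 * ne`) so that linked LD reaches its
#' drift-recombination equilibrium. With `fst > 0` one ancestral pool is
#' equilibrated, duplicated into two islands, and each island drifts for
#' `round(2 * ne * fst)` further generations, the diffusion-scale solution
#' of `fst = t / (2 * ne)`.
#'
#' @param cfg a [simConfig()] object.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return list with `H` (list of phased 0/1 haplotype matrices, one per
#'   subpopulation, rows = `2 * ne` gametes), `map` (marker map
#'   data.frame), `init_freq`, and the config.
#' @export
simulateBasePool <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- .simMap(cfg)
  p <- nrow(map)
  mpc <- cfg$chrom_len_bp / 1e6 * cfg$cm_per_mbp / 100
  f0 <- runif(p)
  H <- matrix(rbinom(2L * cfg$ne * p, 1L, rep(f0, each = 2L * cfg$ne)),
              nrow = 2L * cfg$ne, ncol = p)
  H <- .driftPool(H, cfg$equil_gens, map, mpc, cfg$chrom_len_bp)
  if (cfg$fst > 0) {
    tSplit <- max(1L, round(2 * cfg$ne * cfg$fst))
    pools <- list(
      .driftPool(H, tSplit, map, mpc, cfg$chrom_len_bp),
      .driftPool(H, tSplit, map, mpc, cfg$chrom_len_bp))
  } else {
    pools <- list(H)
  }
  list(H = pools, map = map, init_freq = f0, cfg = cfg)
}

#' Sample open-pollinated half-sib families from the base pool
#'
#' Mothers are drawn without replacement from the adults of each
#' subpopulation (families alternate between islands when structure is on).
#' Every offspring combines one maternal gamete with a pollen gamete from a
#' random non-maternal adult of the same subpopulation, so progeny of one
#' mother are paternal-side unrelated half-sibs with expected additive
#' relationship 0.25. Offspring gametes are summed to 0/1/2 dosages and
#' missing calls are inserted completely at random at `missing_rate`.
#'
#' @param pool output of [simulateBasePool()].
#' @param cfg the same [simConfig()].
#' @param seed optional seed.
#' @return list with `geno` ([GenotypeData-class], missing calls as `NA`),
#'   `complete` (the dosage matrix before missingness), and `pedigree`
#'   (data.frame `id`, `mother`, `subpop`).
#' @export
sampleOpFamilies <- function(pool, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nSub <- length(pool$H)
  famSub <- rep(seq_len(nSub), length.out = cfg$n_families)
  demand <- tabulate(famSub, nSub)
  if (any(demand > cfg$ne))
    stop("family demand exceeds pool: ", max(demand), " mothers needed from ",
         cfg$ne, " adults")
  p <- nrow(pool$map)
  # gametes only need the sites still varying somewhere across the pools;
  # sites fixed everywhere are filled in as constant dosage afterwards
  allH <- do.call(rbind, pool$H)
  cs <- colSums(allH)
  act <- which(cs > 0L & cs < nrow(allH))
  fixedDos <- 2L * as.integer(cs == nrow(allH))
  Hact <- lapply(pool$H, function(h) h[, act, drop = FALSE])
  chromAct <- pool$map$chrom[act]
  ends <- .chromEnds(chromAct)
  morg <- rep(cfg$chrom_len_bp / 1e6 * cfg$cm_per_mbp / 100, length(ends))
  posAct <- pool$map$pos_bp[act]
  mothers <- lapply(seq_len(nSub), function(s) sample.int(cfg$ne, demand[s]))
  nOff <- cfg$n_families * cfg$progeny_per_family
  prog <- cfg$progeny_per_family
  dosAct <- matrix(0L, nOff, length(act))
  ped <- data.frame(id = character(nOff), mother = character(nOff),
                    subpop = integer(nOff), stringsAsFactors = FALSE)
  slot <- setNames(rep(0L, nSub), seq_len(nSub))
  for (f in seq_len(cfg$n_families)) {
    s <- famSub[f]
    slot[s] <- slot[s] + 1L
    mIdx <- mothers[[s]][slot[s]]
    # pollen pool: every non-maternal adult of the mother's subpopulation
    dads <- sample(setdiff(seq_len(cfg$ne), mIdx), prog, replace = TRUE)
    gam <- .wf_gametes_cpp(Hact[[s]], as.integer(rbind(mIdx, dads)), ends,
                           posAct, morg, cfg$chrom_len_bp)
    rows <- (f - 1L) * prog + seq_len(prog)
    dosAct[rows, ] <- gam[seq(1L, 2L * prog, 2L), , drop = FALSE] +
                      gam[seq(2L, 2L * prog, 2L), , drop = FALSE]
    ped$id[rows] <- sprintf("F%02d_%03d", f, seq_len(prog))
    ped$mother[rows] <- sprintf("M%02d", f)
    ped$subpop[rows] <- s
  }
  dos <- matrix(0L, nOff, p)
  one <- which(fixedDos == 2L)
  if (length(one)) dos[, one] <- 2L
  dos[, act] <- dosAct
  rownames(dos) <- ped$id
  colnames(dos) <- pool$map$marker
  obs <- dos
  if (cfg$missing_rate > 0) {
    nMiss <- rbinom(1L, length(obs), cfg$missing_rate)
    obs[sample.int(length(obs), nMiss)] <- NA_integer_
  }
  storage.mode(obs) <- "double"
  list(geno = GenotypeData(obs, pool$map), complete = dos, pedigree = ped)
}

#' Sample random-mating offspring from the base pool
#'
#' Draws `n` offspring, each from two distinct parents picked uniformly in
#' one subpopulation -- one further Wright-Fisher generation, genotyped.
#' This is the sampling design assumed by LD-based effective-size
#' estimation (a random sample of S individuals produced by Ne breeders),
#' as opposed to the family-clustered [sampleOpFamilies()] sample.
#'
#' @param pool output of [simulateBasePool()].
#' @param cfg the same [simConfig()].
#' @param n number of offspring.
#' @param subpop which subpopulation to sample from.
#' @param seed optional seed.
#' @return [GenotypeData-class] of `n` offspring (no missingness).
#' @export
sampleRandomOffspring <- function(pool, cfg, n, subpop = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- pool$H[[subpop]]
  cs <- colSums(H)
  act <- which(cs > 0L & cs < nrow(H))
  fixedDos <- 2L * as.integer(cs == nrow(H))
  chromAct <- pool$map$chrom[act]
  ends <- .chromEnds(chromAct)
  morg <- rep(cfg$chrom_len_bp / 1e6 * cfg$cm_per_mbp / 100, length(ends))
  par1 <- sample.int(cfg$ne, n, replace = TRUE)
  par2 <- vapply(par1, function(m) sample(setdiff(seq_len(cfg$ne), m), 1L),
                 integer(1))
  gam <- .wf_gametes_cpp(H[, act, drop = FALSE],
                         as.integer(rbind(par1, par2)), ends,
                         pool$map$pos_bp[act], morg, cfg$chrom_len_bp)
  dosAct <- gam[seq(1L, 2L * n, 2L), , drop = FALSE] +
            gam[seq(2L, 2L * n, 2L), , drop = FALSE]
  dos <- matrix(0L, n, nrow(pool$map))
  one <- which(fixedDos == 2L)
  if (length(one)) dos[, one] <- 2L
  dos[, act] <- dosAct
  rownames(dos) <- sprintf("R%04d", seq_len(n))
  colnames(dos) <- pool$map$marker
  storage.mode(dos) <- "double"
  GenotypeData(dos, pool$map)
}

#' Simulate an additive trait measured in a randomized complete block design
#'
#' QTL are sampled uniformly among polymorphic markers and given standard
#' normal allelic effects, rescaled so that the in-sample additive variance
#' fraction `Var(a) / (Var(a) + Var(e))` equals `h2_true`. Individuals are
#' laid out one tree per family per block (progeny beyond `n_blocks` wrap
#' around) and block effects `N(0, block_sd^2)` plus an intercept of 10 are
#' added. With `h2_true = 0` the allelic effects are kept at their drawn
#' scale and the residual variance is inflated instead, so the breeding
#' values stay non-degenerate while the heritable fraction is negligible.
#'
#' @param genotypes complete (no missing) dosage matrix, or a
#'   [GenotypeData-class] with no missing calls.
#' @param pedigree pedigree data.frame from [sampleOpFamilies()].
#' @param cfg [simConfig()].
#' @param seed optional seed.
#' @return list with `phen` (data.frame `id`, `family`, `subpop`, `block`,
#'   `trait`) and `truth` (`qtl_markers`, `qtl_effects`, `bv`, `residual`,
#'   `block_effects`, `realized_h2`).
#' @export
simulateTrait <- function(genotypes, pedigree, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- if (is(genotypes, "GenotypeData")) dosages(genotypes) else genotypes
  if (anyNA(M)) stop("simulateTrait needs complete genotypes")
  if (cfg$n_qtl == 0 && cfg$h2_true > 0)
    stop("degenerate request: h2_true > 0 with no QTL")
  n <- nrow(M)
  poly <- which(colMeans(M * M) - colMeans(M)^2 > 1e-12)
  if (cfg$n_qtl > length(poly))
    stop("fewer polymorphic markers than requested QTL")
  qtl <- sort(sample(poly, cfg$n_qtl))
  eff <- rnorm(cfg$n_qtl)
  W <- scale(M[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
  bvRaw <- drop(W %*% eff)
  vRaw <- var(bvRaw)
  if (cfg$h2_true > 0) {
    sc <- sqrt(cfg$h2_true / vRaw)
    bv <- bvRaw * sc
    eff <- eff * sc
    varE <- 1 - cfg$h2_true
  } else {
    sc <- if (vRaw > 0) sqrt(1 / vRaw) else 1
    bv <- bvRaw * sc
    eff <- eff * sc
    varE <- 1e6        # residual inflated, not effects nulled
  }
  e <- rnorm(n, 0, sqrt(varE))
  fam <- factor(pedigree$mother, levels = unique(pedigree$mother))
  withinFam <- stats::ave(seq_len(n), fam, FUN = seq_along)
  block <- ((withinFam - 1L) %% cfg$n_blocks) + 1L
  blockEff <- rnorm(cfg$n_blocks, 0, cfg$block_sd)
  y <- 10 + blockEff[block] + bv + e
  phen <- data.frame(id = pedigree$id, family = pedigree$mother,
                     subpop = pedigree$subpop, block = block, trait = y,
                     stringsAsFactors = FALSE)
  truth <- list(qtl_markers = colnames(M)[qtl], qtl_effects = eff,
                bv = setNames(bv, pedigree$id), residual = e,
                block_effects = blockEff,
                realized_h2 = var(bv) / (var(bv) + var(e)))
  list(phen = phen, truth = truth)
}

#' Synthetic gene-model annotation
#'
#' Tiles each chromosome with non-overlapping gene intervals whose total
#' length covers approximately `genic_fraction` of the chromosome: gene
#' lengths are uniform on 2-8 kb and gap lengths are jittered around
#' `len * (1/fraction - 1)`. A synthetic stand-in for a reference
#' annotation, used only to classify markers as genic or intergenic.
#'
#' @param map marker map data.frame (columns `chrom`, `pos_bp`) or a
#'   [GenotypeData-class]; chromosome extent is taken as the larger of the
#'   last marker position and `chrom_len_bp`.
#' @param genic_fraction target genic coverage in (0, 1).
#' @param chrom_len_bp optional chromosome length (bp).
#' @param seed optional seed.
#' @return a [GenomicRanges::GRanges] of gene intervals (1-based).
#' @export
annotateGenes <- function(map, genic_fraction = 0.5, chrom_len_bp = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (genic_fraction <= 0 || genic_fraction >= 1)
    stop("genic_fraction must be in (0, 1)")
  if (is(map, "GenotypeData")) map <- map@map
  chroms <- unique(map$chrom)
  res <- lapply(chroms, function(ch) {
    len <- max(map$pos_bp[map$chrom == ch])
    if (!is.null(chrom_len_bp)) len <- max(len, chrom_len_bp)
    nEst <- ceiling(len / (5000 / genic_fraction)) + 10
    gl <- round(runif(nEst, 2000, 8000))
    gap <- pmax(round(gl * (1 / genic_fraction - 1) * runif(nEst, 0.7, 1.3)),
                1)
    starts <- 1 + round(runif(1, 0, 2000)) +
      c(0, cumsum(gl + gap))[seq_len(nEst)]
    ends <- pmin(starts + gl - 1, len)
    keep <- starts < len
    data.frame(chrom = ch, start = starts[keep], end = ends[keep])
  })
  df <- do.call(rbind, res)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

#' Classify markers as genic by interval membership
#'
#' @param map marker map data.frame or [GenotypeData-class].
#' @param genes `GRanges` of gene intervals (e.g. [annotateGenes()]).
#' @return logical vector, `TRUE` for markers inside a gene interval.
#' @export
genicMask <- function(map, genes) {
  if (is(map, "GenotypeData")) map <- map@map
  mk <- GenomicRanges::GRanges(map$chrom,
                               IRanges::IRanges(map$pos_bp, map$pos_bp))
  GenomicRanges::countOverlaps(mk, genes) > 0
}

#' Write gene intervals as BED
#'
#' @param genes `GRanges` of gene intervals.
#' @param path output path (BED, 0-based half-open).
#' @export
writeGenesBed <- function(genes, path) {
  rtracklayer::export(genes, path, format = "BED")
  invisible(path)
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper: base-pool drift, open-pollinated family sampling,
#' trait simulation and synthetic gene annotation under one seed. The same
#' seed yields a bit-identical result.
#'
#' @param cfg a [simConfig()]; its `seed` field drives all randomness.
#' @return list with `geno`, `complete`, `pedigree`, `phen`, `truth`,
#'   `genes`, `map`, and the `cfg` echo.
#' @export
simulateStudy <- function(cfg) {
  set.seed(cfg$seed)
  pool <- simulateBasePool(cfg)
  fam <- sampleOpFamilies(pool, cfg)
  tr <- simulateTrait(fam$complete, fam$pedigree, cfg)
  genes <- annotateGenes(pool$map, cfg$genic_fraction,
                         chrom_len_bp = cfg$chrom_len_bp)
  list(geno = fam$geno, complete = fam$complete, pedigree = fam$pedigree,
       phen = tr$phen, truth = tr$truth, genes = genes, map = pool$map,
       cfg = cfg)
}

#' Hudson's Fst between two haplotype pools
#'
#' Ratio-of-averages Hudson estimator from per-site allele frequencies of
#' two pools, used to check that island divergence hits its target.
#'
#' @param H1,H2 0/1 haplotype matrices (rows = gametes).
#' @return scalar Fst estimate.
#' @export
hudsonFst <- function(H1, H2) {
  p1 <- colMeans(H1); p2 <- colMeans(H2)
  n1 <- nrow(H1); n2 <- nrow(H2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}
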