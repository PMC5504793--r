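# Shared fixtures, built in code.

# tiny hand-written genotype set: 6 trees x 5 markers on two chromosomes;
# m3 monomorphic, m4 has 4/6 call rate, m5 carries one missing call
toyGeno <- function() {
  d <- rbind(
    i1 = c(0, 1, 2, NA, 0),
    i2 = c(1, 2, 2, NA, 2),
    i3 = c(2, 0, 2, 1, NA),
    i4 = c(0, 1, 2, 0, 0),
    i5 = c(1, 0, 2, 1, 1),
    i6 = c(2, 2, 2, 0, 2))
  colnames(d) <- paste0("m", 1:5)
  map <- data.frame(marker = paste0("m", 1:5),
                    chrom = c("chr01", "chr01", "chr01", "chr02", "chr02"),
                    pos_bp = c(100, 5000, 250000, 1000, 90000))
  GenotypeData(d, map)
}

# small synthetic study, memoised so several tests can share one build
.studyCache <- new.env(parent = emptyenv())
cachedStudy <- function(key, ...) {
  if (!exists(key, .studyCache)) {
    assign(key, simulateStudy(simConfig(...)), .studyCache)
  }
  get(key, .studyCache)
}

smallStudy <- function() {
  cachedStudy("small", ne = 30, n_chrom = 3, chrom_len_bp = 2e7,
              n_markers = 4000, n_families = 16, progeny_per_family = 12,
              h2_true = 0.4, n_qtl = 80, missing_rate = 0.02,
              cm_per_mbp = 20, seed = 101)
}

structuredStudy <- function() {
  cachedStudy("structured", ne = 30, n_chrom = 4, chrom_len_bp = 2e7,
              n_markers = 6000, n_families = 16, progeny_per_family = 12,
              fst = 0.12, h2_true = 0.4, n_qtl = 60, missing_rate = 0.01,
              cm_per_mbp = 20, seed = 202)
}

blockX <- function(study) treegs:::.blockDesign(study$phen$block)
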