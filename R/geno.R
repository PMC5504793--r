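#' Call-rate and minor-allele-frequency SNP filters
#'
#' Drops markers with call rate below `cr_min` and, on the retained set,
#' applies the frequency filter: with `maf_min = 0` only polymorphic
#' markers are kept (`MAF > 0`, strict), with `maf_min > 0` the boundary is
#' inclusive (`MAF >= maf_min`), matching the usual chip-QC conventions.
#' Counts removed per criterion are reported via `message()`.
#'
#' @param g [GenotypeData-class]
#' @param cr_min minimum call rate kept (boundary kept), in `[0, 1]`.
#' @param maf_min minor-allele-frequency threshold, in `[0, 0.5]`.
#' @return filtered [GenotypeData-class]; the input is untouched.
#' @export
filterSnps <- function(g, cr_min = 0.90, maf_min = 0) {
  stopifnot(cr_min >= 0, cr_min <= 1, maf_min >= 0, maf_min <= 0.5)
  mm <- markerMap(g)
  okCr <- mm$call_rate >= cr_min
  okMaf <- if (maf_min == 0) !is.na(mm$maf) & mm$maf > 0
           else !is.na(mm$maf) & mm$maf >= maf_min
  keep <- okCr & okMaf
  message(sprintf("filterSnps: %d low call rate, %d below MAF threshold, %d retained of %d",
                  sum(!okCr), sum(okCr & !okMaf), sum(keep), nMarkers(g)))
  if (!any(keep)) stop("no markers survive the filters")
  g[, which(keep)]
}

#' Mean imputation of missing genotypes
#'
#' Missing calls are replaced by the observed mean dosage of their marker
#' (a real value in `[0, 2]`); observed entries are unchanged.
#'
#' @param g [GenotypeData-class]
#' @return [GenotypeData-class] with a complete real-valued dosage matrix.
#' @export
imputeMean <- function(g) {
  d <- g@dosage
  if (!anyNA(d)) return(g)
  mu <- colMeans(d, na.rm = TRUE)
  if (anyNA(mu) || any(is.nan(mu)))
    stop("all-missing marker(s) present; filter on call rate first")
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  out <- g
  out@dosage <- d
  out
}

# imputed, centered dosage matrix (columns centered; used by LD and GRMs)
.centeredDosage <- function(g) {
  d <- dosages(imputeMean(g))
  scale(d, center = TRUE, scale = FALSE)
}

#' Windowed LD pruning (PLINK --indep-pairwise style)
#'
#' Greedy within-chromosome pass over markers in map order: for the current
#' marker, every later marker within `window_kb` is examined and from each
#' pair with `r^2 > r2_max` one member is removed -- the one with lower MAF,
#' ties broken by removing the later position. The window then advances by
#' `step_snps`. The surviving set is deterministic given the input order and
#' contains no within-window pair above the threshold. `r^2` is the squared
#' Pearson correlation of mean-imputed dosages.
#'
#' @param g [GenotypeData-class]
#' @param window_kb window width in kb (> 0).
#' @param step_snps SNPs to advance per step (kept for interface parity; the
#'   pass examines every surviving marker regardless).
#' @param r2_max maximum tolerated pairwise `r^2`.
#' @return character vector of retained marker ids.
#' @export
ldPrune <- function(g, window_kb = 100, step_snps = 1, r2_max = 0.2) {
  if (window_kb <= 0) stop("window_kb must be positive")
  mm <- markerMap(g)
  M <- .centeredDosage(g)
  sdv <- sqrt(colMeans(M^2))
  win <- window_kb * 1000
  keepAll <- rep(TRUE, nMarkers(g))
  for (ch in unique(mm$chrom)) {
    idx <- which(mm$chrom == ch)
    pos <- mm$pos_bp[idx]
    keep <- rep(TRUE, length(idx))
    i <- 1L
    while (i <= length(idx)) {
      if (!keep[i]) { i <- i + step_snps; next }
      jmax <- i
      while (jmax < length(idx) && pos[jmax + 1L] - pos[i] <= win)
        jmax <- jmax + 1L
      js <- if (jmax > i) (i + 1L):jmax else integer(0)
      js <- js[keep[js]]
      for (j in js) {
        if (!keep[i]) break
        gi <- idx[i]; gj <- idx[j]
        if (sdv[gi] == 0 || sdv[gj] == 0) next
        r2 <- (mean(M[, gi] * M[, gj]) / (sdv[gi] * sdv[gj]))^2
        if (r2 > r2_max) {
          mi <- mm$maf[gi]; mj <- mm$maf[gj]
          if (is.na(mi)) mi <- 0
          if (is.na(mj)) mj <- 0
          if (mi < mj) keep[i] <- FALSE
          else if (mj < mi) keep[j] <- FALSE
          else keep[j] <- FALSE   # tie: drop the later position
        }
      }
      i <- i + step_snps
    }
    keepAll[idx] <- keep
  }
  mm$marker[keepAll]
}

.subsetLadder <- function(p) {
  base <- c(100, 150, 200, 250, 300, 500, 750, 1000, 1250, 1500, 2000)
  more <- seq(3000, p, by = 1000)
  sort(unique(c(base[base < p], more, p)))
}

#' SNP-subset sampling schemes
#'
#' The six marker-sampling designs used to probe how marker number and
#' placement drive genomic prediction:
#' \describe{
#'   \item{random_stratified_cumulative}{a nested ladder of sizes
#'     (100, 150, 200, 250, 300, 500, 750, 1000, 1250, 1500, 2000, then
#'     1000-SNP steps up to all markers), allocated proportionally per
#'     chromosome, each smaller set contained in the next.}
#'   \item{random_noncumulative}{an independent uniform draw of `size`
#'     markers.}
#'   \item{evenly_spaced}{at most one SNP per non-overlapping window of
#'     `window_bp`, taking the SNP closest to the window midpoint.}
#'   \item{genic / intergenic}{markers inside / outside the gene intervals
#'     of `annotation`.}
#'   \item{ld_pruned}{the [ldPrune()] survivors.}
#'   \item{single_chromosome}{all markers of `chrom`.}
#' }
#'
#' @param g [GenotypeData-class]
#' @param scheme one of the scheme names above.
#' @param size subset size (random schemes).
#' @param sizes optional ladder override for the cumulative scheme.
#' @param window_bp window width (evenly_spaced), e.g. `1e6`.
#' @param chrom chromosome label (single_chromosome).
#' @param annotation `GRanges` of gene intervals (genic / intergenic).
#' @param seed optional seed for the random schemes.
#' @return character vector of marker ids; the cumulative scheme returns a
#'   named list of nested vectors, one per ladder size.
#' @export
sampleSubset <- function(g, scheme, size = NULL, sizes = NULL,
                         window_bp = NULL, chrom = NULL, annotation = NULL,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mm <- markerMap(g)
  p <- nrow(mm)
  scheme <- match.arg(scheme,
    c("random_stratified_cumulative", "random_noncumulative",
      "evenly_spaced", "genic", "intergenic", "ld_pruned",
      "single_chromosome"))
  switch(scheme,
    random_stratified_cumulative = {
      if (is.null(sizes)) sizes <- .subsetLadder(p)
      if (max(sizes) > p) stop("requested size exceeds available markers")
      # fractional within-chromosome rank: a prefix of the global order is a
      # proportionally stratified sample, and prefixes nest by construction
      frac <- numeric(p)
      for (idx in split(seq_len(p), mm$chrom))
        frac[idx] <- (sample(length(idx)) - runif(length(idx))) /
          length(idx)
      ord <- order(frac)
      out <- lapply(sizes, function(s) sort(mm$marker[ord[seq_len(s)]]))
      names(out) <- as.character(sizes)
      out
    },
    random_noncumulative = {
      if (is.null(size)) stop("size required")
      if (size > p) stop("requested size exceeds available markers")
      sort(mm$marker[sample.int(p, size)])
    },
    evenly_spaced = {
      if (is.null(window_bp) || window_bp <= 0) stop("window_bp required")
      pick <- unlist(lapply(split(seq_len(p), mm$chrom), function(idx) {
        w <- (mm$pos_bp[idx] - 1) %/% window_bp
        mid <- w * window_bp + window_bp / 2
        off <- abs(mm$pos_bp[idx] - mid)
        idx[unlist(lapply(split(seq_along(idx), w),
                          function(k) k[which.min(off[k])]))]
      }), use.names = FALSE)
      mm$marker[sort(pick)]
    },
    genic = {
      if (is.null(annotation)) stop("annotation required for genic scheme")
      mm$marker[genicMask(mm, annotation)]
    },
    intergenic = {
      if (is.null(annotation)) stop("annotation required for intergenic scheme")
      mm$marker[!genicMask(mm, annotation)]
    },
    ld_pruned = ldPrune(g),
    single_chromosome = {
      if (is.null(chrom)) stop("chrom required")
      if (!chrom %in% mm$chrom) stop("unknown chromosome: ", chrom)
      mm$marker[mm$chrom == chrom]
    })
}

#' Write a retained-marker list (one id per line)
#'
#' @param ids character marker ids
#' @param path output path
#' @export
writeMarkerIds <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

# ---- genotype I/O -----------------------------------------------------------

#' Read genotypes from a VCF
#'
#' Parses the GT field of a VCF (via `vcfR`) into allele dosages of the ALT
#' allele; biallelic sites only.
#'
#' @param path VCF path (plain or gzipped)
#' @return [GenotypeData-class]
#' @export
readVcfGeno <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  d <- (a1 == "1") + (a2 == "1")
  d[a1 == "." | a2 == "."] <- NA
  fix <- vcfR::getFIX(v)
  map <- data.frame(marker = fix[, "ID"], chrom = fix[, "CHROM"],
                    pos_bp = as.integer(fix[, "POS"]),
                    stringsAsFactors = FALSE)
  noId <- is.na(map$marker) | map$marker == "."
  map$marker[noId] <- paste0(map$chrom[noId], "_", map$pos_bp[noId])
  d <- t(d)
  colnames(d) <- map$marker
  storage.mode(d) <- "double"
  GenotypeData(d, map)
}

#' Write genotypes as a VCF (v4.2, GT only)
#'
#' Dosages are emitted as unphased GT calls with the counted allele as ALT
#' (`0 -> 0/0`, `1 -> 0/1`, `2 -> 1/1`, missing `./.`). Alleles are coded
#' A (REF) / B (ALT) since the simulator carries no nucleotide states.
#'
#' @param g [GenotypeData-class]
#' @param path output path
#' @export
writeVcfGeno <- function(g, path) {
  d <- dosages(g)
  mm <- g@map
  gtCode <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=treegs",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  for (j in seq_len(ncol(d))) {
    gt <- ifelse(is.na(d[, j]), "./.", gtCode[d[, j] + 1])
    writeLines(paste(c(mm$chrom[j], mm$pos_bp[j], mm$marker[j], "A", "B",
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write genotypes as a PLINK-1 binary trio (.bed/.bim/.fam)
#'
#' SNP-major .bed with the standard 2-bit encoding (00 hom A1, 10 het,
#' 11 hom A2, 01 missing), A1 = the counted allele.
#'
#' @param g [GenotypeData-class]
#' @param prefix path prefix (files `prefix.bed/.bim/.fam` are written)
#' @param family optional family id per sample (defaults to sample id)
#' @export
writePlink <- function(g, prefix, family = NULL) {
  d <- dosages(g)
  mm <- g@map
  n <- nrow(d)
  if (is.null(family)) family <- rownames(d)
  write.table(data.frame(family, rownames(d), 0, 0, 0, -9),
              paste0(prefix, ".fam"), quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = " ")
  chromNum <- as.integer(factor(mm$chrom, levels = unique(mm$chrom)))
  write.table(data.frame(chromNum, mm$marker, 0, mm$pos_bp, "B", "A"),
              paste0(prefix, ".bim"), quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  # dosage -> 2-bit code (counted allele is A1): 2->00, 1->10, 0->11, NA->01
  code <- function(x) {
    out <- integer(length(x))
    out[is.na(x)] <- 1L
    out[!is.na(x) & x == 1] <- 2L
    out[!is.na(x) & x == 0] <- 3L
    out
  }
  bytesPerSnp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(ncol(d))) {
    cc <- code(d[, j])
    length(cc) <- bytesPerSnp * 4L
    cc[is.na(cc)] <- 0L
    m <- matrix(cc, nrow = 4)
    writeBin(as.raw(m[1, ] + m[2, ] * 4L + m[3, ] * 16L + m[4, ] * 64L), con)
  }
  invisible(prefix)
}

#' Read a PLINK-1 binary trio
#'
#' @param prefix path prefix of `.bed/.bim/.fam`
#' @return [GenotypeData-class]
#' @export
readPlink <- function(prefix) {
  fam <- read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim <- read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  n <- nrow(fam); p <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK-1 .bed file")
  bytesPerSnp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytesPerSnp * p)
  b <- as.integer(raw)
  two <- matrix(0L, 4, length(b))
  two[1, ] <- b %% 4L
  two[2, ] <- (b %/% 4L) %% 4L
  two[3, ] <- (b %/% 16L) %% 4L
  two[4, ] <- b %/% 64L
  codes <- matrix(as.vector(two), nrow = bytesPerSnp * 4L)[seq_len(n), ,
                                                           drop = FALSE]
  codes <- matrix(codes, nrow = n, ncol = p)
  d <- matrix(NA_real_, n, p)
  d[codes == 0L] <- 2
  d[codes == 2L] <- 1
  d[codes == 3L] <- 0
  rownames(d) <- fam$V2
  colnames(d) <- bim$V2
  map <- data.frame(marker = bim$V2,
                    chrom = sprintf("chr%02d", bim$V1),
                    pos_bp = bim$V4, stringsAsFactors = FALSE)
  GenotypeData(d, map)
}
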