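#' @import methods
#' @importFrom stats var cor sd rnorm runif rbinom rpois qchisq pchisq qbeta
#'   pt qnorm quantile median optimize uniroot kmeans rexp complete.cases
#'   setNames p.adjust cov prcomp coef resid lm
#' @importFrom utils head tail write.table read.table
NULL

#' GenotypeData: SNP dosages with a physical marker map
#'
#' Container for an individuals-by-markers table of minor-allele dosages
#' (0/1/2, `NA` for missing calls) together with the marker map (chromosome
#' and 1-based physical position per marker). This is the object every
#' downstream stage (QC, LD, kinship, prediction, association) consumes.
#'
#' @slot dosage numeric matrix, samples in rows, markers in columns;
#'   dimnames carry sample and marker ids.
#' @slot map `data.frame` with columns `marker`, `chrom`, `pos_bp`;
#'   positions strictly increasing within a chromosome.
#'
#' @aliases GenotypeData-class
#' @exportClass GenotypeData
setClass("GenotypeData",
  representation(dosage = "matrix", map = "data.frame"))

setValidity("GenotypeData", function(object) {
  msg <- character()
  d <- object@dosage
  m <- object@map
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "dosage matrix must carry sample and marker dimnames")
  if (anyDuplicated(rownames(d))) msg <- c(msg, "duplicate sample ids")
  if (anyDuplicated(colnames(d))) msg <- c(msg, "duplicate marker ids")
  if (!all(c("marker", "chrom", "pos_bp") %in% names(m)))
    msg <- c(msg, "map must have columns marker, chrom, pos_bp")
  else {
    if (nrow(m) != ncol(d)) msg <- c(msg, "map length must equal marker count")
    else if (!identical(as.character(m$marker), colnames(d)))
      msg <- c(msg, "map$marker must match dosage colnames in order")
    bad <- unlist(lapply(split(m$pos_bp, m$chrom),
                         function(p) any(diff(p) <= 0)))
    if (any(bad)) msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  # value check bounded to the first 1e6 entries: enough to catch coding
  # errors without an O(n*p) scan on chip-scale panels; real values in
  # [0, 2] are legal (mean-imputed calls)
  v <- d[seq_len(min(length(d), 1e6))]
  v <- v[!is.na(v)]
  if (length(v) && (min(v) < 0 || max(v) > 2))
    msg <- c(msg, "dosages must lie in [0, 2] or be NA")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix of dosages (samples x markers) in {0,1,2,NA};
#'   dimnames are required.
#' @param map data.frame with columns `marker`, `chrom`, `pos_bp` in marker
#'   order (positions 1-based, strictly increasing within chromosome).
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosage, map) {
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  rownames(map) <- NULL
  new("GenotypeData", dosage = dosage, map = map)
}

#' @describeIn GenotypeData-class number of samples
#' @param x,object a `GenotypeData` object
#' @export
nSamples <- function(x) nrow(x@dosage)

#' @describeIn GenotypeData-class number of markers
#' @export
nMarkers <- function(x) ncol(x@dosage)

#' @describeIn GenotypeData-class sample ids
#' @export
sampleIds <- function(x) rownames(x@dosage)

#' @describeIn GenotypeData-class marker ids
#' @export
markerIds <- function(x) colnames(x@dosage)

#' @describeIn GenotypeData-class raw dosage matrix (with `NA` for missing)
#' @export
dosages <- function(x) x@dosage

#' Marker map with per-marker QC statistics
#'
#' Returns the physical map augmented with the two QC axes: minor-allele
#' frequency (folded to `[0, 0.5]`) and call rate, both computed from the
#' current dosage table.
#'
#' @param x a [GenotypeData-class] object
#' @return `data.frame` with columns `marker`, `chrom`, `pos_bp`, `maf`,
#'   `call_rate`.
#' @export
markerMap <- function(x) {
  d <- x@dosage
  cr <- colMeans(!is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  maf <- pmin(af, 1 - af)
  data.frame(x@map, maf = maf, call_rate = cr, row.names = NULL)
}

setMethod("show", "GenotypeData", function(object) {
  mm <- markerMap(object)
  cat("GenotypeData:", nSamples(object), "samples x", nMarkers(object),
      "markers on", length(unique(object@map$chrom)), "chromosome(s)\n")
  cat(sprintf("  missing rate %.3f | median MAF %.3f\n",
              mean(is.na(object@dosage)), median(mm$maf, na.rm = TRUE)))
})

#' Subset a GenotypeData object
#'
#' `x[i, j]` keeps samples `i` and markers `j` (indices, logical masks or
#' ids); the map is subset in step.
#'
#' @param x GenotypeData
#' @param i,j sample / marker selectors
#' @param drop ignored
#' @param ... ignored
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSamples(x))
  if (missing(j)) j <- seq_len(nMarkers(x))
  if (is.character(j)) j <- match(j, colnames(x@dosage))
  if (anyNA(j)) stop("unknown marker ids in subset")
  if (is.logical(j)) j <- which(j)
  d <- x@dosage[i, j, drop = FALSE]
  GenotypeData(d, x@map[j, , drop = FALSE])
})

#' KinshipMatrix: pedigree or genomic relationship matrix
#'
#' Symmetric relationship matrix among individuals, tagged by construction
#' method (`"pedigree_A"`, `"vanraden"`, `"powell"`).
#'
#' @slot values symmetric numeric matrix with sample-id dimnames.
#' @slot method character, construction method.
#' @aliases KinshipMatrix-class
#' @exportClass KinshipMatrix
setClass("KinshipMatrix",
  representation(values = "matrix", method = "character"))

setValidity("KinshipMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  else if (max(abs(v - t(v))) > 1e-10) msg <- c(msg, "matrix must be symmetric")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "dimnames must carry matching sample ids")
  if (!object@method %in% c("pedigree_A", "vanraden", "powell"))
    msg <- c(msg, "unknown construction method")
  if (length(msg)) msg else TRUE
})

#' Construct a KinshipMatrix
#'
#' @param values symmetric numeric matrix with sample-id dimnames.
#' @param method construction method (`"pedigree_A"`, `"vanraden"`,
#'   `"powell"`).
#' @return [KinshipMatrix-class]
#' @export
KinshipMatrix <- function(values, method) {
  values <- (values + t(values)) / 2
  new("KinshipMatrix", values = values, method = method)
}

#' @describeIn KinshipMatrix-class construction method tag
#' @param x,object a `KinshipMatrix`
#' @export
kinshipMethod <- function(x) x@method

#' @export
#' @describeIn KinshipMatrix-class coerce to a base matrix
setMethod("as.matrix", "KinshipMatrix", function(x, ...) x@values)

setMethod("show", "KinshipMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat(sprintf("KinshipMatrix (%s): %d individuals | mean diag %.3f | mean off-diag %.4f\n",
              object@method, nrow(v), mean(diag(v)), mean(off)))
})

#' Write / read a kinship matrix as square TSV
#'
#' Plain-text square table with a header row of ids and ids in the first
#' column; the construction method travels in a `# method:` comment line.
#'
#' @param x KinshipMatrix
#' @param path output path
#' @export
writeKinship <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method: ", x@method), con)
  v <- x@values
  writeLines(paste(c("id", colnames(v)), collapse = "\t"), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], format(v[i, ], digits = 10)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname writeKinship
#' @param path input path
#' @export
readKinship <- function(path) {
  first <- readLines(path, n = 1L)
  method <- sub("^# method: *", "", first)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    row.names = 1, check.names = FALSE)
  KinshipMatrix(as.matrix(tab), method = method)
}
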