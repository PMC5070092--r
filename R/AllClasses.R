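#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<- seqinfo Seqinfo
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Pooled allele counts for two sequencing pools
#'
#' `PooledCounts` holds biallelic SNP sites with per-pool ref/alt read counts,
#' the atomic input of the sex-patterned SNP analysis. It extends
#' [SummarizedExperiment::RangedSummarizedExperiment-class]: rows are width-1
#' genomic sites (with `ref` and `alt` alleles in `mcols()`), columns are the
#' two pools, and the `"ref"` and `"alt"` assays carry the read counts. Column
#' metadata records each pool's `role`: `"het"` for the heterogametic-sex pool
#' (males in an XY system) and `"hom"` for the homogametic-sex pool. Which pool
#' plays which role is declared by the caller, never inferred, so WZ systems
#' are supported by swapping the roles.
#'
#' @slot .Data see `RangedSummarizedExperiment`
#' @seealso [PooledCounts()] for the constructor, [readSyncTable()],
#'   [readPooledVcf()], [scanSites()]
#' @export
setClass("PooledCounts", contains = "RangedSummarizedExperiment")

setValidity("PooledCounts", function(object) {
    msg <- character()
    if (!all(c("ref", "alt") %in% names(assays(object))))
        msg <- c(msg, "assays must contain 'ref' and 'alt' read counts")
    if (ncol(object) != 2L)
        msg <- c(msg, "exactly two pools (columns) are required")
    if (!identical(sort(as.character(colData(object)$role)), c("het", "hom")))
        msg <- c(msg, "colData$role must be exactly {'het','hom'}")
    if (nrow(object) > 0L) {
        rr <- rowRanges(object)
        if (!all(width(rr) == 1L))
            msg <- c(msg, "all sites must have width 1")
        mc <- mcols(rr)
        if (!all(c("ref", "alt") %in% names(mc))) {
            msg <- c(msg, "rowRanges mcols must contain 'ref' and 'alt' alleles")
        } else {
            if (!all(mc$ref %in% DNA_BASES) || !all(mc$alt %in% DNA_BASES))
                msg <- c(msg, "ref and alt alleles must be one of A/C/G/T")
            if (any(mc$ref == mc$alt))
                msg <- c(msg, "ref and alt alleles must differ at every site")
        }
        key <- paste(seqnames(rr), start(rr))
        if (anyDuplicated(key))
            msg <- c(msg, "(chrom, pos) must be unique within a dataset")
        for (a in c("ref", "alt")) {
            m <- assay(object, a)
            if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
                msg <- c(msg, sprintf("assay '%s' must hold non-negative integer counts", a))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PooledCounts object
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt reference and alternate alleles (single bases, `ref != alt`).
#' @param hetRef,hetAlt read counts of ref and alt in the heterogametic pool.
#' @param homRef,homAlt read counts of ref and alt in the homogametic pool.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return a [PooledCounts-class] object; input order is preserved.
#' @examples
#' pc <- PooledCounts("chr1", 100L, "A", "G", 18L, 12L, 30L, 0L)
#' refCounts(pc)
#' @export
PooledCounts <- function(chrom, pos, ref, alt, hetRef, hetAlt, homRef, homAlt,
                         seqlengths = NULL) {
    n <- length(pos)
    stopifnot(length(chrom) %in% c(1L, n), length(ref) == n, length(alt) == n)
    gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L),
                  ref = as.character(ref), alt = as.character(alt))
    if (!is.null(seqlengths))
        seqlengths(gr) <- seqlengths[seqlevels(gr)]
    refM <- cbind(het = as.integer(hetRef), hom = as.integer(homRef))
    altM <- cbind(het = as.integer(hetAlt), hom = as.integer(homAlt))
    se <- SummarizedExperiment(
        assays = list(ref = refM, alt = altM),
        rowRanges = gr,
        colData = DataFrame(role = c("het", "hom"), row.names = c("het", "hom")))
    methods::new("PooledCounts", se)
}

#' @describeIn PooledCounts sites reordered by (chrom, pos)
#' @export
sortSites <- function(x) {
    o <- order(as.factor(seqnames(rowRanges(x))), start(rowRanges(x)))
    x[o, ]
}

isSortedSites <- function(x) {
    o <- order(as.factor(seqnames(rowRanges(x))), start(rowRanges(x)))
    identical(o, seq_len(nrow(x)))
}

#' @describeIn PooledCounts ref-allele read counts (sites x pools matrix)
#' @param x a `PooledCounts` object
#' @export
refCounts <- function(x) assay(x, "ref")

#' @describeIn PooledCounts alt-allele read counts (sites x pools matrix)
#' @export
altCounts <- function(x) assay(x, "alt")

#' @describeIn PooledCounts per-pool sequencing depth (ref + alt)
#' @export
poolDepth <- function(x) assay(x, "ref") + assay(x, "alt")

#' @describeIn PooledCounts reference and alternate alleles as a data.frame
#' @export
siteAlleles <- function(x) {
    mc <- mcols(rowRanges(x))
    data.frame(ref = mc$ref, alt = mc$alt)
}

setMethod("show", "PooledCounts", function(object) {
    cat(sprintf("PooledCounts with %d biallelic site%s on %d sequence%s\n",
                nrow(object), if (nrow(object) == 1L) "" else "s",
                length(seqlevels(object)),
                if (length(seqlevels(object)) == 1L) "" else "s"))
    if (nrow(object) > 0L) {
        d <- colMeans(poolDepth(object))
        cat(sprintf("mean depth: het pool %.1f, hom pool %.1f\n",
                    d[["het"]], d[["hom"]]))
    }
})

#' Detector parameters for sex-patterned SNP classification
#'
#' Thresholds governing which sites are called sex-patterned. A site is
#' sex-patterned when one allele is fixed or nearly fixed (minor-allele
#' frequency at most `homogFixedMax`) in the homogametic pool while the other
#' allele segregates at intermediate frequency (within `[hetLow, hetHigh]`,
#' closed interval) in the heterogametic pool, supported by at least
#' `minAlleleCount` reads there. Sites where either pool has depth below
#' `minDepth` are not evaluated. `maxCoverage` bounds Nei's D at alternatively
#' fixed sites: frequencies of exactly 0 and 1 are replaced by
#' `1/maxCoverage` and `1 - 1/maxCoverage` so that D stays finite.
#'
#' @param hetLow,hetHigh closed bounds of the intermediate-frequency band in
#'   the heterogametic pool (defaults 0.3 and 0.7).
#' @param homogFixedMax maximum minor-allele frequency still counted as
#'   "nearly fixed" in the homogametic pool (default 0.1).
#' @param minDepth minimum per-pool read depth for a site to be evaluated
#'   (default 10).
#' @param minAlleleCount minimum read count of the candidate sex-linked allele
#'   in the heterogametic pool (default 2).
#' @param maxCoverage user-specified coverage ceiling used to clamp Nei's D at
#'   alternatively fixed sites (default 100).
#' @return a `DetectorParams` object.
#' @examples
#' detectorParams()
#' detectorParams(minDepth = 20)
#' @export
detectorParams <- function(hetLow = 0.3, hetHigh = 0.7, homogFixedMax = 0.1,
                           minDepth = 10L, minAlleleCount = 2L,
                           maxCoverage = 100L) {
    methods::new("DetectorParams", hetLow = hetLow, hetHigh = hetHigh,
                 homogFixedMax = homogFixedMax, minDepth = as.integer(minDepth),
                 minAlleleCount = as.integer(minAlleleCount),
                 maxCoverage = as.integer(maxCoverage))
}

#' @rdname detectorParams
#' @export
setClass("DetectorParams", representation(
    hetLow = "numeric", hetHigh = "numeric", homogFixedMax = "numeric",
    minDepth = "integer", minAlleleCount = "integer", maxCoverage = "integer"))

setValidity("DetectorParams", function(object) {
    msg <- character()
    if (!(object@hetLow >= 0 && object@hetLow < object@hetHigh &&
          object@hetHigh <= 1))
        msg <- c(msg, "need 0 <= hetLow < hetHigh <= 1")
    if (!(object@homogFixedMax >= 0 && object@homogFixedMax < object@hetLow))
        msg <- c(msg, "need 0 <= homogFixedMax < hetLow")
    if (object@minDepth < 1L) msg <- c(msg, "minDepth must be >= 1")
    if (object@minAlleleCount < 0L) msg <- c(msg, "minAlleleCount must be >= 0")
    if (object@maxCoverage < 2L) msg <- c(msg, "maxCoverage must be >= 2")
    if (length(msg)) msg else TRUE
})

setMethod("show", "DetectorParams", function(object) {
    cat("DetectorParams\n")
    cat(sprintf("  heterogametic frequency band: [%.2f, %.2f]\n",
                object@hetLow, object@hetHigh))
    cat(sprintf("  homogametic max minor freq:   %.2f\n", object@homogFixedMax))
    cat(sprintf("  min depth %d, min allele count %d, max coverage %d\n",
                object@minDepth, object@minAlleleCount, object@maxCoverage))
})

#' Configuration of the pooled XY read-sampling simulator
#'
#' Describes the study design the simulator emulates: a single-family XY cross
#' sequenced as one male and one female pool. Defaults follow a 21-male /
#' 22-female pooled design at ~35x per-pool coverage. Inside `sdRegion`, Y-linked
#' sex-patterned sites are planted at rate `sdSnpRate` per bp; everywhere,
#' background (non-sex-linked) SNPs arise at `backgroundSnpRate` per bp with a
#' shared allele frequency drawn uniformly from {0.1, ..., 0.9} in both pools.
#' Per-pool site depth is Poisson(`meanCoverage`); read counts are binomial in
#' the chromosome-level allele frequency. All males being XY, the male-pool
#' chromosome-level Y frequency at a sex-patterned site is exactly 0.5.
#' Sequencing error is off by default and available as a per-base flip
#' probability.
#'
#' @param chromLengths named integer vector, chromosome -> length in bp.
#' @param nMales,nFemales numbers of individuals pooled (defaults 21 and 22).
#' @param meanCoverage mean per-pool depth (default 35).
#' @param sdRegion a [GenomicRanges::GRanges] of length 1 harbouring the Y
#'   haplotype, or `NULL` for none.
#' @param backgroundSnpRate per-bp probability of a background SNP.
#' @param sdSnpRate per-bp probability of a Y-linked sex-patterned site inside
#'   `sdRegion`.
#' @param errorRate per-base sequencing-error flip probability (default 0).
#' @param seed integer RNG seed.
#' @return a `SimConfig` object.
#' @examples
#' simConfig(c(chr1 = 1e6), sdRegion = GenomicRanges::GRanges("chr1:1-2e5"),
#'           backgroundSnpRate = 1e-4, sdSnpRate = 1e-3, seed = 1)
#' @export
simConfig <- function(chromLengths, nMales = 21L, nFemales = 22L,
                      meanCoverage = 35, sdRegion = NULL,
                      backgroundSnpRate = 0, sdSnpRate = 0,
                      errorRate = 0, seed = 1L) {
    if (is.null(sdRegion)) sdRegion <- GRanges()
    methods::new("SimConfig",
                 chromLengths = structure(as.integer(chromLengths),
                                          names = names(chromLengths)),
                 nMales = as.integer(nMales), nFemales = as.integer(nFemales),
                 meanCoverage = as.numeric(meanCoverage), sdRegion = sdRegion,
                 backgroundSnpRate = backgroundSnpRate, sdSnpRate = sdSnpRate,
                 errorRate = errorRate, seed = as.integer(seed))
}

#' @rdname simConfig
#' @export
setClass("SimConfig", representation(
    chromLengths = "integer", nMales = "integer", nFemales = "integer",
    meanCoverage = "numeric", sdRegion = "GRanges",
    backgroundSnpRate = "numeric", sdSnpRate = "numeric",
    errorRate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (is.null(names(object@chromLengths)) || any(object@chromLengths < 1L))
        msg <- c(msg, "chromLengths must be a named vector of positive lengths")
    if (object@nMales < 1L || object@nFemales < 1L)
        msg <- c(msg, "nMales and nFemales must be >= 1")
    if (object@meanCoverage <= 0) msg <- c(msg, "meanCoverage must be positive")
    rates <- c(object@backgroundSnpRate, object@sdSnpRate, object@errorRate)
    if (any(rates < 0) || any(rates > 1))
        msg <- c(msg, "rates must lie in [0, 1]")
    if (length(object@sdRegion) > 1L)
        msg <- c(msg, "sdRegion must be empty or a single interval")
    if (length(object@sdRegion) == 1L) {
        chr <- as.character(seqnames(object@sdRegion))
        if (!chr %in% names(object@chromLengths))
            msg <- c(msg, "sdRegion chromosome absent from chromLengths")
        else if (end(object@sdRegion) > object@chromLengths[[chr]])
            msg <- c(msg, "sdRegion extends beyond its chromosome")
    }
    if (length(object@sdRegion) == 0L && object@sdSnpRate > 0)
        msg <- c(msg, "sdSnpRate > 0 requires a non-empty sdRegion")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", sum(object@chromLengths), "bp over",
        length(object@chromLengths), "chromosome(s);",
        object@nMales, "males /", object@nFemales, "females at",
        object@meanCoverage, "x\n")
    if (length(object@sdRegion))
        cat("  SD region:", as.character(object@sdRegion), "\n")
})

#' JASPAR-style position frequency matrix
#'
#' Raw base counts of a transcription-factor binding motif: a 4 x L matrix
#' with rows A, C, G, T. Parsed from JASPAR 2016 text files by
#' [readJasparPfm()]; converted to a log-odds scoring matrix by [pfmToPwm()].
#'
#' @param matrixID motif identifier (e.g. "MA0482.1").
#' @param name transcription-factor name (e.g. "Gata4").
#' @param counts 4 x L non-negative numeric matrix, rows in A,C,G,T order.
#' @return a `PFMatrix` object.
#' @examples
#' pfm <- PFMatrix("TOY.1", "toy", matrix(c(10, 0, 0, 0, 0, 10, 0, 0), 4,
#'                 dimnames = list(c("A", "C", "G", "T"), NULL)))
#' motifLength(pfm)
#' @export
PFMatrix <- function(matrixID, name, counts) {
    counts <- as.matrix(counts)
    rownames(counts) <- DNA_BASES
    methods::new("PFMatrix", matrixID = matrixID, name = name, counts = counts)
}

#' @rdname PFMatrix
#' @export
setClass("PFMatrix", representation(
    matrixID = "character", name = "character", counts = "matrix"))

setValidity("PFMatrix", function(object) {
    msg <- character()
    cn <- object@counts
    if (nrow(cn) != 4L || ncol(cn) < 1L)
        msg <- c(msg, "counts must be a 4 x L matrix with L >= 1")
    if (any(cn < 0)) msg <- c(msg, "counts must be non-negative")
    if (nrow(cn) == 4L && any(colSums(cn) <= 0))
        msg <- c(msg, "every column must have a positive total")
    if (length(msg)) msg else TRUE
})

#' @describeIn PFMatrix motif length L
#' @param x a `PFMatrix` or `PWMatrix`
#' @export
motifLength <- function(x) ncol(if (methods::is(x, "PFMatrix")) x@counts else x@matrix)

#' @describeIn PFMatrix motif identifier
#' @export
motifID <- function(x) x@matrixID

setMethod("show", "PFMatrix", function(object) {
    cat(sprintf("PFMatrix %s (%s), length %d\n", object@matrixID,
                object@name, ncol(object@counts)))
})

#' Position weight (log-odds) matrix
#'
#' Built from a [PFMatrix-class] by [pfmToPwm()]; holds per-cell log2
#' likelihood ratios against the background, plus the minimum and maximum
#' attainable window scores used to place raw scores on the JASPAR relative
#' scale `(raw - scoreMin) / (scoreMax - scoreMin)`.
#'
#' @seealso [pfmToPwm()], [scanSequence()]
#' @export
setClass("PWMatrix", representation(
    matrixID = "character", name = "character", matrix = "matrix",
    scoreMin = "numeric", scoreMax = "numeric",
    pseudocount = "numeric", background = "numeric"))

setMethod("show", "PWMatrix", function(object) {
    cat(sprintf("PWMatrix %s (%s), length %d, score range [%.3f, %.3f]\n",
                object@matrixID, object@name, ncol(object@matrix),
                object@scoreMin, object@scoreMax))
})
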