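#' Cp: half the L1 distance between two allele-frequency vectors
#'
#' Cp ranges from 0 (no population differentiation, identical frequency
#' vectors) to 1 (complete differentiation, disjoint allele support):
#' \deqn{C_p = \sum_i \frac{1}{2} |x_i - y_i|}
#' For a biallelic site this reduces to `|p_x - p_y|`, the absolute difference
#' of the alt-allele frequencies.
#'
#' @param x,y allele-frequency vectors over the same allele set (same length;
#'   if named, same names), each summing to 1.
#' @return Cp in `[0, 1]`.
#' @examples
#' computeCp(c(1, 0), c(0, 1))        # 1: disjoint support
#' computeCp(c(0.5, 0.5), c(1, 0))    # 0.5
#' @export
computeCp <- function(x, y) {
    if (length(x) != length(y))
        abort("frequency vectors are over different allele sets")
    if (!is.null(names(x)) && !is.null(names(y)) &&
        !identical(names(x), names(y)))
        abort("frequency vectors are over different allele sets")
    tol <- 1e-6
    if (abs(sum(x) - 1) > tol || abs(sum(y) - 1) > tol)
        abort("frequency vectors must each sum to 1")
    sum(abs(x - y)) / 2
}

# corrected within-pool heterozygosity (n/(n-1)) * 2p(1-p); 0 when monomorphic
poolPi <- function(ref, alt) {
    n <- ref + alt
    p <- alt / n
    h <- 2 * p * (1 - p)
    ifelse(h == 0, 0, n / (n - 1) * h)
}

#' Per-site FST between two pools
#'
#' The pi-based per-site estimator: within-pool nucleotide diversity
#' `pi = n/(n-1) * 2p(1-p)` is computed for each pool (`n` = read depth,
#' `p` = alt frequency), `pi_S` is their mean, `pi_T` is computed identically
#' from the summed counts, and `FST = (pi_T - pi_S) / pi_T`. Because the
#' bias-correction factor shrinks with depth, two pools with identical count
#' vectors give `pi_T` marginally below `pi_S`; such negative estimates carry
#' no differentiation signal and are truncated at 0, so identical pools
#' report exactly 0. `NA` when either pool has depth below 2 or when
#' `pi_T = 0` (site monomorphic overall); undefined values are reported as
#' missing, never as 0.
#'
#' @param hetRef,hetAlt,homRef,homAlt read-count vectors for the two pools
#'   (vectorised over sites).
#' @return numeric vector of FST values, `NA` where undefined.
#' @examples
#' computeFst(20, 20, 40, 0)   # ~0.325
#' computeFst(10, 10, 10, 10)  # 0: identical pools
#' @export
computeFst <- function(hetRef, hetAlt, homRef, homAlt) {
    n1 <- hetRef + hetAlt
    n2 <- homRef + homAlt
    piS <- (poolPi(hetRef, hetAlt) + poolPi(homRef, homAlt)) / 2
    piT <- poolPi(hetRef + homRef, hetAlt + homAlt)
    fst <- pmax((piT - piS) / piT, 0)
    fst[n1 < 2 | n2 < 2 | piT == 0] <- NA_real_
    fst
}

#' Per-site dxy and da between two pools
#'
#' `dxy` is the probability that one read drawn from each pool differs:
#' `dxy = p1(1-p2) + p2(1-p1)` with `p1`, `p2` the pools' alt frequencies.
#' `da` nets out mean within-pool diversity: `da = dxy - (pi1 + pi2)/2`, with
#' the same bias-corrected `pi` used by [computeFst()]. `NA` at zero depth.
#'
#' @inheritParams computeFst
#' @return a data.frame with columns `dxy` and `da`.
#' @examples
#' computeDxyDa(20, 20, 40, 0)  # dxy = 0.5, da ~ 0.244
#' @export
computeDxyDa <- function(hetRef, hetAlt, homRef, homAlt) {
    n1 <- hetRef + hetAlt
    n2 <- homRef + homAlt
    p1 <- hetAlt / n1
    p2 <- homAlt / n2
    dxy <- p1 * (1 - p2) + p2 * (1 - p1)
    da <- dxy - (poolPi(hetRef, hetAlt) + poolPi(homRef, homAlt)) / 2
    bad <- n1 < 1 | n2 < 1
    dxy[bad] <- NA_real_
    da[bad] <- NA_real_
    data.frame(dxy = dxy, da = da)
}

#' Per-site Nei's genetic distance D
#'
#' `D = -ln I` with the normalised identity
#' `I = sum(x_i y_i) / sqrt(sum(x_i^2) sum(y_i^2))` over the two pools'
#' allele-frequency vectors. At alternatively fixed sites `I = 0` and D is
#' infinite, so there the frequencies 0 and 1 are first replaced by
#' `1/maxCoverage` and `1 - 1/maxCoverage`; partially fixed sites are left
#' untouched. `D >= 0` always (Cauchy-Schwarz).
#'
#' @inheritParams computeFst
#' @param maxCoverage coverage ceiling used for the clamp (default 100).
#' @return numeric vector of D values, `NA` at zero depth.
#' @examples
#' computeNeiD(20, 0, 0, 20)  # alternatively fixed: ~3.90 at maxCoverage 100
#' @export
computeNeiD <- function(hetRef, hetAlt, homRef, homAlt, maxCoverage = 100) {
    n1 <- hetRef + hetAlt
    n2 <- homRef + homAlt
    p1 <- hetAlt / n1
    p2 <- homAlt / n2
    altFixed <- (p1 == 0 & p2 == 1) | (p1 == 1 & p2 == 0)
    eps <- 1 / maxCoverage
    clamp <- function(p) ifelse(altFixed,
                                pmin(pmax(p, eps), 1 - eps), p)
    p1 <- clamp(p1)
    p2 <- clamp(p2)
    num <- p1 * p2 + (1 - p1) * (1 - p2)
    den <- sqrt((p1^2 + (1 - p1)^2) * (p2^2 + (1 - p2)^2))
    d <- -log(num / den)
    d <- pmax(d, 0)  # guard tiny negative rounding at I ~ 1
    d[n1 < 1 | n2 < 1] <- NA_real_
    d
}

#' Classify a single site as sex-patterned or not
#'
#' A site is sex-patterned when (a) one allele is fixed or nearly fixed
#' (frequency at least `1 - homogFixedMax`) in the homogametic pool, (b) the
#' other allele segregates at a frequency within `[hetLow, hetHigh]` (closed)
#' in the heterogametic pool, and (c) that allele — the candidate Y (or W)
#' allele — is supported by at least `minAlleleCount` reads in the
#' heterogametic pool. Sites where either pool's depth is below `minDepth`
#' are not evaluated.
#'
#' @inheritParams computeFst
#' @param params a [detectorParams()] object.
#' @return a data.frame with columns `evaluated`, `sex_patterned`, and the
#'   candidate-Y branch: `y_is_alt` (`TRUE` if the sex-linked allele is the
#'   alt allele, `FALSE` if ref, `NA` if not sex-patterned).
#' @examples
#' classifySite(18, 12, 30, 0, detectorParams())  # sex-patterned, Y = alt
#' @export
classifySite <- function(hetRef, hetAlt, homRef, homAlt,
                         params = detectorParams()) {
    n1 <- hetRef + hetAlt
    n2 <- homRef + homAlt
    evaluated <- n1 >= params@minDepth & n2 >= params@minDepth
    pHetAlt <- ifelse(n1 > 0, hetAlt / n1, NA_real_)
    pHomAlt <- ifelse(n2 > 0, homAlt / n2, NA_real_)
    inBand <- function(p) !is.na(p) & p >= params@hetLow & p <= params@hetHigh
    # homogametic pool ~fixed for ref => candidate Y allele is alt
    yAlt <- !is.na(pHomAlt) & pHomAlt <= params@homogFixedMax &
        inBand(pHetAlt) & hetAlt >= params@minAlleleCount
    # homogametic pool ~fixed for alt => candidate Y allele is ref
    yRef <- !is.na(pHomAlt) & pHomAlt >= 1 - params@homogFixedMax &
        inBand(1 - pHetAlt) & hetRef >= params@minAlleleCount
    sexPatterned <- evaluated & (yAlt | yRef)
    data.frame(evaluated = evaluated, sex_patterned = sexPatterned,
               y_is_alt = ifelse(sexPatterned, yAlt, NA))
}

#' Scan a pooled dataset: per-site statistics and sex-pattern classification
#'
#' Single pass over a [PooledCounts-class] computing, for every site, the
#' pools' alt-allele frequencies, the five differentiation statistics (FST,
#' dxy, da, Nei's D, Cp) and the sex-patterned classification of
#' [classifySite()]. For sex-patterned sites the inferred X allele (the one
#' fixed/near-fixed in the homogametic pool) and Y allele (the intermediate
#' one in the heterogametic pool) are recorded.
#'
#' @param x a [PooledCounts-class], sorted by (chrom, pos); unsorted input is
#'   an error (use [sortSites()]).
#' @param params a [detectorParams()] object.
#' @param quiet suppress the per-class summary message.
#' @return a [GenomicRanges::GRanges] (one range per input site, same order)
#'   with metadata columns `ref`, `alt`, `p_het`, `p_hom`, `fst`, `dxy`, `da`,
#'   `nei_d`, `cp`, `sex_patterned`, `evaluated`, `x_allele`, `y_allele`.
#' @examples
#' pc <- PooledCounts("chr1", c(100L, 200L), c("A", "C"), c("G", "T"),
#'                    c(18L, 20L), c(12L, 0L), c(30L, 25L), c(0L, 0L))
#' scanSites(pc, quiet = TRUE)
#' @export
scanSites <- function(x, params = detectorParams(), quiet = FALSE) {
    stopifnot(methods::is(x, "PooledCounts"))
    if (!isSortedSites(x))
        abort("sites must be sorted by (chrom, pos); see sortSites()")
    gr <- granges(rowRanges(x))
    al <- siteAlleles(x)
    hetRef <- refCounts(x)[, "het"]; hetAlt <- altCounts(x)[, "het"]
    homRef <- refCounts(x)[, "hom"]; homAlt <- altCounts(x)[, "hom"]
    n1 <- hetRef + hetAlt
    n2 <- homRef + homAlt
    pHet <- ifelse(n1 > 0, hetAlt / n1, NA_real_)
    pHom <- ifelse(n2 > 0, homAlt / n2, NA_real_)
    cls <- classifySite(hetRef, hetAlt, homRef, homAlt, params)
    dd <- computeDxyDa(hetRef, hetAlt, homRef, homAlt)
    mcols(gr) <- DataFrame(
        ref = al$ref, alt = al$alt,
        p_het = pHet, p_hom = pHom,
        fst = computeFst(hetRef, hetAlt, homRef, homAlt),
        dxy = dd$dxy, da = dd$da,
        nei_d = computeNeiD(hetRef, hetAlt, homRef, homAlt,
                            params@maxCoverage),
        cp = abs(pHet - pHom),
        sex_patterned = cls$sex_patterned,
        evaluated = cls$evaluated,
        x_allele = ifelse(cls$sex_patterned,
                          ifelse(cls$y_is_alt, al$ref, al$alt), NA_character_),
        y_allele = ifelse(cls$sex_patterned,
                          ifelse(cls$y_is_alt, al$alt, al$ref), NA_character_))
    if (!quiet)
        message(sprintf(
            "scanSites: %d sites; %d evaluated; %d sex-patterned",
            length(gr), sum(cls$evaluated), sum(cls$sex_patterned)))
    gr
}

#' Write per-site statistics as TSV
#'
#' Columns: chrom, pos, ref, alt, p_het, p_hom, fst, dxy, da, nei_d, cp,
#' sex_patterned, evaluated, x_allele, y_allele. Undefined statistics are
#' written as `NA`, never 0, so downstream averages over polymorphic sites
#' can exclude them.
#'
#' @param stats output of [scanSites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSiteStats <- function(stats, path) {
    df <- data.frame(chrom = as.character(seqnames(stats)),
                     pos = start(stats),
                     as.data.frame(mcols(stats)))
    writeResultsTsv(df, path)
}

#' Read per-site statistics written by [writeSiteStats()]
#'
#' @param path file path.
#' @return a `GRanges` equivalent to the [scanSites()] output.
#' @export
readSiteStats <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                            comment.char = "", stringsAsFactors = FALSE,
                            colClasses = list(x_allele = "character",
                                              y_allele = "character"))
    gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L))
    mcols(gr) <- DataFrame(df[setdiff(names(df), c("chrom", "pos"))])
    gr
}
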