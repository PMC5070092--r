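#' Infer the X and Y alleles of a sex-patterned site
#'
#' The X allele is the one fixed or nearly fixed in the homogametic pool; the
#' Y allele is the other one, segregating at intermediate frequency in the
#' heterogametic pool. The inference is invariant under ref/alt relabelling.
#' An error is raised for sites that are not sex-patterned.
#'
#' @param stats a [scanSites()] result.
#' @return data.frame with columns `x_allele`, `y_allele`, one row per site.
#' @export
inferXYAlleles <- function(stats) {
    if (!all(mcols(stats)$sex_patterned %in% TRUE))
        abort("inferXYAlleles requires sex-patterned sites only")
    data.frame(x_allele = mcols(stats)$x_allele,
               y_allele = mcols(stats)$y_allele)
}

#' Intersect two species' sex-patterned SNPs and classify allele consistency
#'
#' Takes the per-site scans of two species on a shared reference coordinate
#' system and reports every position sex-patterned in both. Each shared site
#' is classified from its four inferred alleles, checking in order:
#' `CONSERVED` (same X and same Y allele in both species), `SWITCHED` (the X
#' allele of one species is the Y allele of the other and vice versa),
#' `SAME_X_DIFF_Y` (same X, different Y), else `OTHER`. The classes are
#' mutually exclusive.
#'
#' @param statsA,statsB [scanSites()] results for species A and B, each
#'   sorted by (chrom, pos).
#' @return data.frame with columns `chrom`, `pos`, `x_a`, `y_a`, `x_b`,
#'   `y_b`, `class`.
#' @export
intersectAndClassify <- function(statsA, statsB) {
    for (s in list(statsA, statsB)) {
        o <- order(as.factor(seqnames(s)), start(s))
        if (!identical(o, seq_along(s)))
            abort("inputs must be sorted by (chrom, pos)")
    }
    a <- statsA[mcols(statsA)$sex_patterned %in% TRUE]
    b <- statsB[mcols(statsB)$sex_patterned %in% TRUE]
    keyA <- paste(seqnames(a), start(a))
    keyB <- paste(seqnames(b), start(b))
    i <- match(keyA, keyB)
    hit <- which(!is.na(i))
    if (!length(hit))
        return(data.frame(chrom = character(), pos = integer(),
                          x_a = character(), y_a = character(),
                          x_b = character(), y_b = character(),
                          class = character()))
    a <- a[hit]; b <- b[i[hit]]
    xa <- mcols(a)$x_allele; ya <- mcols(a)$y_allele
    xb <- mcols(b)$x_allele; yb <- mcols(b)$y_allele
    cls <- ifelse(xa == xb & ya == yb, "CONSERVED",
           ifelse(xa == yb & ya == xb, "SWITCHED",
           ifelse(xa == xb & ya != yb, "SAME_X_DIFF_Y", "OTHER")))
    data.frame(chrom = as.character(seqnames(a)), pos = start(a),
               x_a = xa, y_a = ya, x_b = xb, y_b = yb, class = cls)
}

#' Null expectation for the number of shared sex-patterned SNPs
#'
#' Under independence, the expected number of positions sex-patterned in both
#' species within a region of length `L` bp is the product of the two per-bp
#' frequencies times the region size:
#' `(n_a / L) * (n_b / L) * L = n_a * n_b / L`.
#'
#' @param nA,nB sex-patterned SNP counts of the two species in the region.
#' @param regionLengthBp region length in bp (> 0).
#' @return list with `n_a`, `n_b`, `length_bp`, `expected` (unrounded) and
#'   `expected_2dp` (rounded half-up to 2 decimals).
#' @examples
#' expectedShared(5342, 10792, 8800000)$expected_2dp  # 6.55
#' @export
expectedShared <- function(nA, nB, regionLengthBp) {
    if (regionLengthBp <= 0) abort("region length must be positive")
    e <- nA * nB / regionLengthBp
    list(n_a = nA, n_b = nB, length_bp = regionLengthBp,
         expected = e, expected_2dp = roundHalfUp(e, 2))
}

#' Partition shared-SNP records among named regions
#'
#' Each record is assigned to the first region containing its position, or to
#' `"other"` (e.g. unanchored scaffolds) when none does. Counts always sum to
#' the number of input records.
#'
#' @param records output of [intersectAndClassify()].
#' @param regions named list of `GRanges`.
#' @return list with `records` (input plus a `region` column) and `counts`
#'   (table of records per region label).
#' @export
filterByRegion <- function(records, regions) {
    lab <- rep("other", nrow(records))
    if (nrow(records)) {
        pts <- GRanges(records$chrom, IRanges(records$pos, width = 1L))
        for (nm in rev(names(regions)))
            lab[IRanges::overlapsAny(pts, regions[[nm]])] <- nm
    }
    records$region <- lab
    counts <- table(factor(lab, levels = c(names(regions), "other")))
    list(records = records, counts = counts)
}
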