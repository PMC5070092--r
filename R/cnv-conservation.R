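#' Direction-call copy-number segments by log2-ratio threshold
#'
#' A segment is an amplification when `log2_ratio >= ampThreshold` and a
#' deletion when `log2_ratio <= -delThreshold` (both inclusive, so a ratio of
#' exactly 0.2 is called at the default thresholds); everything in between is
#' dropped.
#'
#' @param segments a `GRanges` from [readVarscanSegments()] (mcol
#'   `log2_ratio`).
#' @param ampThreshold,delThreshold non-negative thresholds (defaults 0.2).
#' @return the called subset with an added `direction` mcol (`"AMP"`/`"DEL"`).
#' @export
thresholdSegments <- function(segments, ampThreshold = 0.2,
                              delThreshold = 0.2) {
    if (ampThreshold < 0 || delThreshold < 0)
        abort("thresholds must be non-negative")
    lr <- mcols(segments)$log2_ratio
    dir <- ifelse(lr >= ampThreshold, "AMP",
                  ifelse(lr <= -delThreshold, "DEL", NA))
    keep <- !is.na(dir)
    out <- segments[keep]
    mcols(out)$direction <- dir[keep]
    out
}

#' Conserved copy-number variants across n comparisons
#'
#' A conserved CNV is a maximal genomic interval covered, in every one of the
#' `n` tracks, by at least one segment of the same direction; the reported
#' interval is the intersection of the covering segments. Equivalently, a
#' base belongs to a conserved AMP (DEL) iff every track calls it AMP (DEL).
#' With `minSupport < n` the requirement relaxes to "called in at least
#' `minSupport` tracks".
#'
#' @param tracks list (length >= 2) of direction-called `GRanges` from
#'   [thresholdSegments()].
#' @param minSupport minimum number of supporting tracks (default: all).
#' @return a sorted `GRanges` with mcols `direction` and `support`;
#'   non-overlapping within each direction.
#' @examples
#' t1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 599), direction = "AMP")
#' t2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(300, 899), direction = "AMP")
#' conservedCnvs(list(t1, t2))  # AMP chr1:300-599
#' @export
conservedCnvs <- function(tracks, minSupport = length(tracks)) {
    if (length(tracks) < 2L) abort("need at least 2 tracks")
    stopifnot(minSupport >= 1L, minSupport <= length(tracks))
    out <- GRanges()
    for (dir in c("AMP", "DEL")) {
        covs <- lapply(tracks, function(t)
            GenomicRanges::reduce(t[mcols(t)$direction == dir]))
        if (minSupport == length(tracks)) {
            shared <- Reduce(GenomicRanges::intersect, covs)
        } else {
            cov <- GenomicRanges::coverage(do.call(c, unname(covs)))
            shared <- GRanges(IRanges::slice(cov, lower = minSupport,
                                             rangesOnly = TRUE))
        }
        if (length(shared)) {
            mcols(shared)$direction <- dir
            mcols(shared)$support <- minSupport
            out <- c(out, shared)
        }
    }
    GenomicRanges::sort(out)
}

#' Per-window density of conserved CNVs with gap-aware lengths
#'
#' Counts conserved CNVs per fixed non-overlapping window (a CNV straddling a
#' boundary is counted once, in the window containing its midpoint) and
#' normalises by the window's effective (non-gap) length. Windows lying
#' entirely inside assembly gaps get an `NA` density and should be excluded
#' from downstream tests.
#'
#' @param conserved output of [conservedCnvs()].
#' @param windowSize window span in bp (default 10000).
#' @param gaps `GRanges` of assembly gaps, or empty.
#' @param chromLengths named vector of chromosome lengths; defaults to the
#'   span of the supplied CNVs.
#' @return a `GRanges` of windows with mcols `n_cnv`, `effective_len`,
#'   `density_per_mb`.
#' @export
cnvWindowDensity <- function(conserved, windowSize = 10000, gaps = GRanges(),
                             chromLengths = NULL) {
    if (is.null(chromLengths)) {
        if (!length(conserved)) abort("supply chromLengths for empty input")
        chromLengths <- vapply(
            split(end(conserved), as.character(seqnames(conserved))),
            max, numeric(1))
    }
    mid <- GRanges(seqnames(conserved),
                   IRanges(grMidpoint(conserved), width = 1L))
    fake <- GRanges(names(chromLengths)[1], IRanges(1, width = 1),
                    sex_patterned = FALSE)
    windows <- windowCounts(fake, windowSize, gaps, chromLengths)
    n <- GenomicRanges::countOverlaps(windows, mid)
    eff <- mcols(windows)$effective_len
    dens <- ifelse(eff > 0, n / (eff / 1e6), NA_real_)
    mcols(windows) <- DataFrame(n_cnv = n, effective_len = eff,
                                density_per_mb = dens)
    windows
}

#' Write conserved CNVs as TSV
#'
#' @param conserved output of [conservedCnvs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConservedCnvs <- function(conserved, path) {
    df <- data.frame(chrom = as.character(seqnames(conserved)),
                     start = start(conserved), end = end(conserved),
                     direction = mcols(conserved)$direction,
                     support = mcols(conserved)$support)
    writeResultsTsv(df, path)
}
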