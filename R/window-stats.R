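#' Tile chromosomes into fixed non-overlapping windows and count site classes
#'
#' Windows are anchored at coordinate 0 on every chromosome; a site at 1-based
#' position `pos` falls in window `floor((pos - 1)/windowSize)`, so position
#' 10000 belongs to the first 10 kb window and 10001 to the second. The
#' trailing partial window is kept with its true length. Each window records
#' the number of sex-patterned sites, the total number of sites, and an
#' effective length equal to the window span minus its overlap with assembly
#' gaps.
#'
#' @param stats a [scanSites()] result (GRanges with `sex_patterned` mcol).
#' @param windowSize window span in bp (default 10000).
#' @param gaps a `GRanges` of assembly gaps (see [readBedGaps()]), or empty.
#' @param chromLengths optional named vector of chromosome lengths; defaults
#'   to `seqlengths(stats)` where set, else the last observed site position.
#' @return a `GRanges` of windows with mcols `n_sex_patterned`,
#'   `n_total_snps`, `effective_len`, `enriched` (`NA` until
#'   [callEnriched()]).
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 10001), width = 1),
#'                              sex_patterned = c(TRUE, FALSE))
#' windowCounts(gr, chromLengths = c(chr1 = 20000))
#' @export
windowCounts <- function(stats, windowSize = 10000, gaps = GRanges(),
                         chromLengths = NULL) {
    if (windowSize <= 0) abort("windowSize must be positive")
    if (is.null(chromLengths)) {
        sl <- seqlengths(stats)
        chromLengths <- sl[!is.na(sl)]
        obs <- tapply(end(stats), as.character(seqnames(stats)), max)
        for (chr in names(obs))
            if (!chr %in% names(chromLengths))
                chromLengths[chr] <- obs[[chr]]
    }
    if (!length(chromLengths)) abort("no chromosome lengths available")
    win <- list()
    for (chr in names(chromLengths)) {
        L <- chromLengths[[chr]]
        st <- seq(1L, L, by = windowSize)
        win[[chr]] <- GRanges(chr, IRanges(st, pmin(st + windowSize - 1L, L)))
    }
    windows <- do.call(c, unname(win))
    hitAll <- GenomicRanges::countOverlaps(windows, stats)
    sp <- stats[mcols(stats)$sex_patterned %in% TRUE]
    hitSp <- GenomicRanges::countOverlaps(windows, sp)
    eff <- width(windows)
    if (length(gaps)) {
        ov <- GenomicRanges::findOverlaps(windows, GenomicRanges::reduce(gaps))
        if (length(ov)) {
            w <- width(IRanges::pintersect(
                IRanges::ranges(windows)[S4Vectors::queryHits(ov)],
                IRanges::ranges(GenomicRanges::reduce(gaps))[S4Vectors::subjectHits(ov)]))
            gapBp <- tapply(w, S4Vectors::queryHits(ov), sum)
            eff[as.integer(names(gapBp))] <-
                eff[as.integer(names(gapBp))] - as.integer(gapBp)
        }
    }
    mcols(windows) <- DataFrame(n_sex_patterned = hitSp, n_total_snps = hitAll,
                                effective_len = as.integer(eff),
                                enriched = rep(NA, length(windows)))
    windows
}

#' Flag windows enriched for sex-patterned SNPs
#'
#' A window is enriched when it contains at least `minSnps` sex-patterned
#' SNPs (inclusive: a window with exactly `minSnps` qualifies).
#'
#' @param windows output of [windowCounts()].
#' @param minSnps enrichment threshold (default 10).
#' @return `windows` with the `enriched` mcol filled in.
#' @export
callEnriched <- function(windows, minSnps = 10) {
    mcols(windows)$enriched <- mcols(windows)$n_sex_patterned >= minSnps
    windows
}

#' Complement of a set of regions over the genome
#'
#' Utility for "rest of the genome" comparisons: everything outside the given
#' regions.
#'
#' @param regions a `GRanges` (or list of `GRanges`) to exclude.
#' @param chromLengths named vector of chromosome lengths.
#' @return a `GRanges` covering the complement.
#' @export
restOfGenome <- function(regions, chromLengths) {
    if (is.list(regions)) regions <- do.call(c, unname(regions))
    genome <- GRanges(names(chromLengths),
                      IRanges(1L, as.integer(chromLengths)))
    GenomicRanges::setdiff(genome, regions)
}

#' Summarise a genomic region: mean FST and sex-patterned SNP densities
#'
#' For one region (one or more intervals) computes the mean per-site FST over
#' all sites with defined FST (polymorphic sites, not only sex-patterned
#' ones), the count and per-Mb density of sex-patterned SNPs, the count and
#' density of enriched windows (assigned by window midpoint), and — when a
#' functional-annotation table is supplied — counts and densities of
#' missense, deleterious (PROVEAN score < -2.5) and synonymous sex-patterned
#' SNPs. Densities are count per Mb of region span; report formatting rounds
#' them half-up to 2 decimals.
#'
#' @param stats a [scanSites()] result.
#' @param windows output of [callEnriched()].
#' @param region a `GRanges` of non-overlapping intervals.
#' @param label region label for the output row.
#' @param annotations optional data.frame (`chrom`, `pos`, `effect`,
#'   `provean_score`), e.g. from [simulateAnnotations()].
#' @return a one-row data.frame (`RegionSummary`).
#' @export
summarizeRegion <- function(stats, windows, region, label = "region",
                            annotations = NULL) {
    if (!length(region) || sum(width(region)) == 0)
        abort("zero-length region")
    if (!GenomicRanges::isDisjoint(region))
        abort("region intervals must be non-overlapping")
    lengthBp <- sum(as.numeric(width(region)))
    mb <- lengthBp / 1e6
    inReg <- IRanges::overlapsAny(stats, region)
    s <- stats[inReg]
    fst <- mcols(s)$fst
    meanFst <- if (any(!is.na(fst))) mean(fst, na.rm = TRUE) else NA_real_
    nSp <- sum(mcols(s)$sex_patterned %in% TRUE)
    mid <- GRanges(seqnames(windows), IRanges(grMidpoint(windows), width = 1L))
    winIn <- IRanges::overlapsAny(mid, region)
    nEnr <- sum(mcols(windows)$enriched[winIn] %in% TRUE)
    out <- data.frame(label = label, length_bp = lengthBp,
                      mean_fst_polymorphic = meanFst,
                      n_sex_patterned = nSp, density_per_mb = nSp / mb,
                      n_enriched_windows = nEnr,
                      enriched_density_per_mb = nEnr / mb)
    if (!is.null(annotations)) {
        spSites <- s[mcols(s)$sex_patterned %in% TRUE]
        key <- paste(annotations$chrom, annotations$pos)
        hit <- match(paste(seqnames(spSites), start(spSites)), key)
        eff <- annotations$effect[hit[!is.na(hit)]]
        prov <- annotations$provean_score[hit[!is.na(hit)]]
        nMis <- sum(eff == "missense")
        nDel <- sum(eff == "missense" & !is.na(prov) & prov < -2.5)
        nSyn <- sum(eff == "synonymous")
        out$n_missense <- nMis; out$missense_per_mb <- nMis / mb
        out$n_deleterious <- nDel; out$deleterious_per_mb <- nDel / mb
        out$n_synonymous <- nSyn; out$synonymous_per_mb <- nSyn / mb
    }
    out
}

#' Mann-Whitney U test for two samples of window counts
#'
#' U is computed from rank sums with midranks at ties. The two-sided p-value
#' is exact — by full enumeration of all assignments of the pooled
#' observations to the two groups — when `n_a + n_b <= 16` and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b numeric vectors (e.g. per-window sex-patterned SNP counts).
#' @return list with `U` (statistic for sample `a`) and `p.value`
#'   (two-sided).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(a, b) {
    if (!length(a) || !length(b)) abort("both samples must be non-empty")
    na <- length(a); nb <- length(b)
    pooled <- c(a, b)
    r <- rank(pooled)
    U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    ties <- anyDuplicated(pooled) > 0L
    if (na + nb <= 16L && !ties) {
        # exact null distribution of U by enumerating all group assignments
        idx <- utils::combn(na + nb, na)
        us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
        pLe <- mean(us <= U)
        pGe <- mean(us >= U)
        p <- min(1, 2 * min(pLe, pGe))
    } else {
        mu <- na * nb / 2
        tieTab <- table(pooled)
        n <- na + nb
        sig2 <- na * nb / 12 *
            ((n + 1) - sum(tieTab^3 - tieTab) / (n * (n - 1)))
        if (sig2 <= 0) return(list(U = U, p.value = 1))
        z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
        p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    list(U = U, p.value = p)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`, reported rounded (half-up) to 6 decimals; with the defaults
#' (`alpha = 0.05` over `m = 12` comparisons) this is 0.004167.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of comparisons (default 12).
#' @return corrected threshold.
#' @examples
#' bonferroniAlpha()          # 0.004167
#' bonferroniAlpha(0.01, 4)   # 0.0025
#' @export
bonferroniAlpha <- function(alpha = 0.05, m = 12L) {
    if (m < 1) abort("m must be >= 1")
    roundHalfUp(alpha / m, 6)
}

#' Compare per-window densities between pairs of regions
#'
#' For each pair of disjoint regions, collects the window values (windows are
#' assigned to a region when their midpoint falls inside it), runs the
#' two-sided [mannWhitneyU()] test, and flags significance at the
#' Bonferroni-corrected threshold `alpha/m`.
#'
#' @param windows output of [windowCounts()]/[callEnriched()].
#' @param regionPairs a list; each element a list with `label_a`, `region_a`
#'   (GRanges), `label_b`, `region_b`.
#' @param alpha,m family-wise error rate and number of comparisons (defaults
#'   0.05 and 12).
#' @param value name of the window mcol to compare (default
#'   `"n_sex_patterned"`).
#' @return data.frame with one row per pair: labels, sample sizes, `U`, `p`,
#'   `significant`.
#' @export
compareRegions <- function(windows, regionPairs, alpha = 0.05, m = 12L,
                           value = "n_sex_patterned") {
    thr <- bonferroniAlpha(alpha, m)
    mid <- GRanges(seqnames(windows), IRanges(grMidpoint(windows), width = 1L))
    rows <- lapply(regionPairs, function(pr) {
        if (length(GenomicRanges::intersect(pr$region_a, pr$region_b)) > 0)
            abort("regions within a pair must be disjoint (",
                  pr$label_a, " vs ", pr$label_b, ")")
        va <- mcols(windows)[[value]][IRanges::overlapsAny(mid, pr$region_a)]
        vb <- mcols(windows)[[value]][IRanges::overlapsAny(mid, pr$region_b)]
        mw <- mannWhitneyU(va, vb)
        data.frame(label_a = pr$label_a, label_b = pr$label_b,
                   n_a = length(va), n_b = length(vb),
                   U = mw$U, p = mw$p.value,
                   significant = mw$p.value < thr)
    })
    if (!length(rows))
        return(data.frame(label_a = character(), label_b = character(),
                          n_a = integer(), n_b = integer(), U = numeric(),
                          p = numeric(), significant = logical()))
    do.call(rbind, rows)
}
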