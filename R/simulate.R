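#' @importFrom stats rbinom rpois runif setNames
NULL

# draw read counts for a table of sites given chromosome-level frequencies;
# pHet/pHom are alt-allele frequencies. Returns integer count columns.
drawPoolReads <- function(n, pHet, pHom, meanCoverage, errorRate = 0) {
    dHet <- rpois(n, meanCoverage)
    dHom <- rpois(n, meanCoverage)
    hetAlt <- rbinom(n, dHet, pHet)
    homAlt <- rbinom(n, dHom, pHom)
    hetRef <- dHet - hetAlt
    homRef <- dHom - homAlt
    if (errorRate > 0) {
        # a ref read flips to alt and vice versa with the given probability
        flip <- function(refN, altN) {
            r2a <- rbinom(n, refN, errorRate)
            a2r <- rbinom(n, altN, errorRate)
            cbind(refN - r2a + a2r, altN - a2r + r2a)
        }
        het <- flip(hetRef, hetAlt); hom <- flip(homRef, homAlt)
        hetRef <- het[, 1]; hetAlt <- het[, 2]
        homRef <- hom[, 1]; homAlt <- hom[, 2]
    }
    data.frame(hetRef = hetRef, hetAlt = hetAlt,
               homRef = homRef, homAlt = homAlt)
}

# sample SNP positions on one chromosome at a per-bp rate, optionally
# restricted to [from, to] (1-based inclusive)
samplePositions <- function(rate, from, to) {
    L <- to - from + 1L
    if (L <= 0L || rate <= 0) return(integer())
    k <- rbinom(1L, L, rate)
    if (k == 0L) return(integer())
    sort(sample.int(L, k)) + from - 1L
}

# random ref/alt pairs; X allele is either ref or alt with equal probability
sampleAlleles <- function(n) {
    ref <- sample(DNA_BASES, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), "")
    data.frame(ref = ref, alt = unname(alt))
}

# build the per-site truth table for one species' genome under a SimConfig.
# Sex-patterned sites: all female chromosomes carry X; male chromosome-level
# Y frequency is exactly nMales/(2*nMales) = 0.5 (every male is XY).
# Background sites: one shared frequency from {0.1,...,0.9} in both pools.
simTruth <- function(config) {
    rows <- list()
    sdChr <- if (length(config@sdRegion))
        as.character(seqnames(config@sdRegion)) else NA_character_
    for (chr in names(config@chromLengths)) {
        L <- config@chromLengths[[chr]]
        sdPos <- integer()
        if (identical(chr, sdChr) && config@sdSnpRate > 0)
            sdPos <- samplePositions(config@sdSnpRate,
                                     start(config@sdRegion),
                                     end(config@sdRegion))
        bgPos <- samplePositions(config@backgroundSnpRate, 1L, L)
        bgPos <- setdiff(bgPos, sdPos)
        n <- length(sdPos) + length(bgPos)
        if (n == 0L) next
        pos <- c(sdPos, bgPos)
        cat_ <- c(rep("sex_patterned_Y", length(sdPos)),
                  rep("background", length(bgPos)))
        al <- sampleAlleles(n)
        yIsAlt <- c(runif(length(sdPos)) < 0.5, rep(NA, length(bgPos)))
        bgFreq <- sample(seq(0.1, 0.9, by = 0.1), length(bgPos),
                         replace = TRUE)
        pHet <- c(rep(0.5, length(sdPos)), bgFreq)
        pHom <- c(rep(0, length(sdPos)), bgFreq)
        # frequencies above are for the Y (or minor) allele; express as alt
        altHet <- ifelse(is.na(yIsAlt), pHet, ifelse(yIsAlt, pHet, 1 - pHet))
        altHom <- ifelse(is.na(yIsAlt), pHom, ifelse(yIsAlt, pHom, 1 - pHom))
        df <- data.frame(chrom = chr, pos = pos, category = cat_,
                         ref = al$ref, alt = al$alt,
                         x_allele = ifelse(is.na(yIsAlt), NA,
                                           ifelse(yIsAlt, al$ref, al$alt)),
                         y_allele = ifelse(is.na(yIsAlt), NA,
                                           ifelse(yIsAlt, al$alt, al$ref)),
                         p_het_alt = altHet, p_hom_alt = altHom)
        o <- order(df$pos)
        rows[[chr]] <- df[o, ]
    }
    if (!length(rows))
        return(data.frame(chrom = character(), pos = integer(),
                          category = character(), ref = character(),
                          alt = character(), x_allele = character(),
                          y_allele = character(), p_het_alt = numeric(),
                          p_hom_alt = numeric()))
    do.call(rbind, c(rows, make.row.names = FALSE))
}

# counts from a truth table
truthToCounts <- function(truth, config) {
    rc <- drawPoolReads(nrow(truth), truth$p_het_alt, truth$p_hom_alt,
                        config@meanCoverage, config@errorRate)
    PooledCounts(truth$chrom, truth$pos, truth$ref, truth$alt,
                 rc$hetRef, rc$hetAlt, rc$homRef, rc$homAlt,
                 seqlengths = config@chromLengths)
}

#' Simulate pooled read counts from an XY cross with known truth
#'
#' Emulates the pooled study design encoded in a [simConfig()]: Y-linked
#' sex-patterned sites inside the sex-determination region (female-pool
#' chromosomes all carry the X allele; male-pool chromosome-level Y frequency
#' exactly 0.5), background SNPs at a shared frequency drawn uniformly from
#' {0.1, ..., 0.9} in both pools, per-pool depth Poisson(`meanCoverage`) and
#' binomial read sampling. Deterministic under the config's seed.
#'
#' @param config a [simConfig()] object.
#' @return a list with elements `counts` (a [PooledCounts-class], sorted) and
#'   `truth` (a data.frame with one row per emitted site: `chrom`, `pos`,
#'   `category` of `sex_patterned_Y`/`background`, alleles, true X/Y alleles,
#'   and the chromosome-level alt-allele frequencies in each pool).
#' @examples
#' cfg <- simConfig(c(chr1 = 5e4), sdRegion = GenomicRanges::GRanges("chr1:1-5e4"),
#'                  sdSnpRate = 1e-3, seed = 7)
#' sim <- simulatePools(cfg)
#' table(sim$truth$category)
#' @export
simulatePools <- function(config) {
    methods::validObject(config)
    set.seed(config@seed)
    truth <- simTruth(config)
    counts <- truthToCounts(truth, config)
    list(counts = counts, truth = truth)
}

#' Simulate a species pair sharing an ancestral sex-determination region
#'
#' Two pooled datasets whose sex-determination regions descend from a common
#' ancestor with partial lineage sorting of Y alleles. A fraction
#' `sharedFraction` of species A's SD-region sex-patterned positions are also
#' sex-patterned in species B; the shared set is partitioned (deterministic
#' rounding) into `switchFraction` sites whose X and Y alleles are exchanged
#' between species, `yReplaceFraction` sites where species B carries a
#' different Y allele on the same X, and a conserved remainder with identical
#' X and Y alleles. Non-shared SD sites, and all background sites, are
#' private to each species.
#'
#' @param configA,configB [simConfig()] objects; their `sdRegion`s must
#'   overlap (shared positions are drawn from the overlap).
#' @param sharedFraction fraction of ancestral SD sites present in both
#'   species.
#' @param switchFraction,yReplaceFraction fractions *of the shared set* that
#'   are allele-switched or Y-replaced (must sum to <= 1).
#' @param seed integer seed (overrides the configs' seeds for the pair draw).
#' @return list with `a`, `b` (each a `simulatePools()`-style list) and
#'   `shared_truth`, a data.frame of shared positions with columns `chrom`,
#'   `pos`, `class` (`CONSERVED`/`SWITCHED`/`SAME_X_DIFF_Y`) and the four
#'   alleles.
#' @export
simulateSpeciesPair <- function(configA, configB, sharedFraction,
                                switchFraction = 0, yReplaceFraction = 0,
                                seed = configA@seed) {
    stopifnot(sharedFraction >= 0, sharedFraction <= 1,
              switchFraction >= 0, yReplaceFraction >= 0)
    if (switchFraction + yReplaceFraction > 1)
        abort("switchFraction + yReplaceFraction must be <= 1")
    if (!length(configA@sdRegion) || !length(configB@sdRegion))
        abort("both configs need a non-empty sdRegion")
    ov <- GenomicRanges::intersect(configA@sdRegion, configB@sdRegion)
    if (!length(ov))
        abort("the two sdRegions do not overlap")
    set.seed(seed)
    truthA <- simTruth(configA)
    truthB <- simTruth(configB)
    # candidate ancestral sites: species A's SD sites inside the overlap
    inOv <- truthA$category == "sex_patterned_Y" &
        truthA$chrom == as.character(seqnames(ov)) &
        truthA$pos >= start(ov) & truthA$pos <= end(ov)
    cand <- which(inOv)
    nShared <- round(length(cand) * sharedFraction)
    sharedIdx <- if (nShared > 0L) sort(sample(cand, nShared)) else integer()
    nSwitch <- round(nShared * switchFraction)
    nRepl <- round(nShared * yReplaceFraction)
    cls <- c(rep("SWITCHED", nSwitch), rep("SAME_X_DIFF_Y", nRepl),
             rep("CONSERVED", nShared - nSwitch - nRepl))
    cls <- if (nShared) sample(cls) else character()
    sharedRows <- list()
    for (k in seq_along(sharedIdx)) {
        i <- sharedIdx[k]
        xa <- truthA$x_allele[i]; ya <- truthA$y_allele[i]
        if (cls[k] == "CONSERVED") { xb <- xa; yb <- ya }
        else if (cls[k] == "SWITCHED") { xb <- ya; yb <- xa }
        else { xb <- xa; yb <- sample(setdiff(DNA_BASES, c(xa, ya)), 1L) }
        # species B is biallelic {xb, yb}; keep species A's ref where possible
        refB <- if (truthA$ref[i] %in% c(xb, yb)) truthA$ref[i] else xb
        altB <- setdiff(c(xb, yb), refB)
        sharedRows[[k]] <- data.frame(
            chrom = truthA$chrom[i], pos = truthA$pos[i], class = cls[k],
            x_a = xa, y_a = ya, x_b = xb, y_b = yb,
            ref = refB, alt = altB,
            x_allele = xb, y_allele = yb,
            p_het_alt = ifelse(altB == yb, 0.5, 0.5),
            p_hom_alt = ifelse(altB == yb, 0, 1))
    }
    shared <- if (length(sharedRows)) do.call(rbind, sharedRows) else
        data.frame(chrom = character(), pos = integer(), class = character(),
                   x_a = character(), y_a = character(),
                   x_b = character(), y_b = character())
    # species B keeps its private sites away from every species-A
    # sex-patterned position (private SD sets stay disjoint), then gains the
    # shared SD sites with the class-determined alleles
    spA <- truthA$category == "sex_patterned_Y"
    drop <- paste(truthB$chrom, truthB$pos) %in%
        paste(truthA$chrom[spA], truthA$pos[spA])
    truthB <- truthB[!drop, ]
    if (nrow(shared)) {
        add <- data.frame(chrom = shared$chrom, pos = shared$pos,
                          category = "sex_patterned_Y",
                          ref = shared$ref, alt = shared$alt,
                          x_allele = shared$x_allele,
                          y_allele = shared$y_allele,
                          p_het_alt = ifelse(shared$alt == shared$y_allele,
                                             0.5, 0.5),
                          p_hom_alt = ifelse(shared$alt == shared$y_allele,
                                             0, 1))
        truthB <- rbind(truthB, add)
        truthB <- truthB[order(truthB$chrom, truthB$pos), ]
    }
    countsA <- truthToCounts(truthA, configA)
    countsB <- truthToCounts(truthB, configB)
    list(a = list(counts = countsA, truth = truthA),
         b = list(counts = countsB, truth = truthB),
         shared_truth = shared[, c("chrom", "pos", "class",
                                   "x_a", "y_a", "x_b", "y_b")])
}

#' Simulate VarScan-style copy-number tracks with planted conserved CNVs
#'
#' Produces `nComparisons` collections of copy-number segments. Every true
#' CNV appears in all tracks with `|log2 ratio| >= 0.2` and consistent sign,
#' its boundaries jittered by at most `jitter` bp per track; noise segments
#' (spurious calls) appear in single tracks only and avoid the true
#' intervals. Segment lengths respect the 100 bp - 1 kb window bounds of the
#' upstream caller, except that true CNV intervals are emitted at their own
#' length.
#'
#' @param nComparisons number of tracks (pairwise comparisons), >= 1.
#' @param trueCnvs a [GenomicRanges::GRanges] of planted CNVs with an mcol
#'   `direction` of `"AMP"`/`"DEL"`.
#' @param noiseRate expected number of noise segments per track.
#' @param jitter maximum boundary jitter in bp (default 0).
#' @param chromLengths named vector of chromosome lengths (for noise
#'   placement); defaults to 10 kb past the last true CNV.
#' @param seed integer seed.
#' @return list with `tracks` (list of `GRanges` with VarScan-style mcols)
#'   and `truth` (the input `trueCnvs`).
#' @export
simulateCnvTracks <- function(nComparisons, trueCnvs, noiseRate = 0,
                              jitter = 0, chromLengths = NULL, seed = 1L) {
    stopifnot(nComparisons >= 1)
    set.seed(seed)
    if (is.null(chromLengths)) {
        chromLengths <- vapply(split(end(trueCnvs), as.character(seqnames(trueCnvs))),
                               max, numeric(1)) + 10000
    }
    mkSeg <- function(chrom, st, en, lr) {
        GRanges(chrom, IRanges(st, en),
                n_positions = pmax(1L, as.integer((en - st + 1) %/% 10)),
                depth1 = rep(35, length(st)), depth2 = rep(35, length(st)),
                log2_ratio = lr)
    }
    tracks <- vector("list", nComparisons)
    for (t in seq_len(nComparisons)) {
        segs <- GRanges()
        if (length(trueCnvs)) {
            j1 <- if (jitter > 0) sample(-jitter:jitter, length(trueCnvs),
                                         TRUE) else 0L
            j2 <- if (jitter > 0) sample(-jitter:jitter, length(trueCnvs),
                                         TRUE) else 0L
            st <- pmax(1L, start(trueCnvs) + j1)
            en <- pmax(st, end(trueCnvs) + j2)
            sgn <- ifelse(mcols(trueCnvs)$direction == "AMP", 1, -1)
            lr <- sgn * runif(length(trueCnvs), 0.3, 1.0)
            segs <- mkSeg(as.character(seqnames(trueCnvs)), st, en, lr)
        }
        nNoise <- rpois(1L, noiseRate)
        k <- 0L
        while (k < nNoise) {
            chrom <- sample(names(chromLengths), 1L)
            len <- sample(100:1000, 1L)
            st <- sample.int(max(1L, chromLengths[[chrom]] - len), 1L)
            cand <- GRanges(chrom, IRanges(st, st + len - 1L))
            if (length(trueCnvs) &&
                length(GenomicRanges::findOverlaps(cand, trueCnvs)) > 0)
                next
            lr <- sample(c(-1, 1), 1L) * runif(1L, 0.25, 0.8)
            segs <- c(segs, mkSeg(chrom, start(cand), end(cand), lr))
            k <- k + 1L
        }
        tracks[[t]] <- GenomicRanges::sort(segs)
    }
    list(tracks = tracks, truth = trueCnvs)
}

#' Simulate a mock functional-annotation table for sex-patterned SNPs
#'
#' Assigns each supplied site an effect class (missense / synonymous /
#' noncoding) and, for missense sites, a PROVEAN-style score, so Table-style
#' per-region effect densities can be exercised without external annotation
#' tools. Purely synthetic labels.
#'
#' @param stats a [scanSites()] result (or any GRanges of sites).
#' @param pMissense,pSynonymous class probabilities (remainder noncoding).
#' @param seed integer seed.
#' @return data.frame with `chrom`, `pos`, `effect`, `provean_score`.
#' @export
simulateAnnotations <- function(stats, pMissense = 0.02, pSynonymous = 0.03,
                                seed = 1L) {
    set.seed(seed)
    n <- length(stats)
    eff <- sample(c("missense", "synonymous", "noncoding"), n, TRUE,
                  prob = c(pMissense, pSynonymous, 1 - pMissense - pSynonymous))
    score <- ifelse(eff == "missense", round(runif(n, -6, 2), 2), NA_real_)
    data.frame(chrom = as.character(seqnames(stats)), pos = start(stats),
               effect = eff, provean_score = score)
}

#' Write a simulation truth table as TSV
#'
#' @param truth a truth data.frame from [simulatePools()] or
#'   [simulateSpeciesPair()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(truth, path) writeResultsTsv(truth, path)
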