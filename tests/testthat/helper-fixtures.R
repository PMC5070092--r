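suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

# site stats from raw counts, via the full scan
makeStats <- function(chrom, pos, ref, alt, hetRef, hetAlt, homRef, homAlt,
                      params = detectorParams()) {
    pc <- PooledCounts(chrom, as.integer(pos), ref, alt,
                       as.integer(hetRef), as.integer(hetAlt),
                       as.integer(homRef), as.integer(homAlt))
    scanSites(sortSites(pc), params, quiet = TRUE)
}

writeSyncLines <- function(rows, path = tempfile(fileext = ".tsv")) {
    hdr <- "chrom\tpos\tref\talt\tpool1_ref\tpool1_alt\tpool2_ref\tpool2_alt"
    writeLines(c(hdr, rows), path)
    path
}

# a one-hot PFM: consensus given as a base string
onehotPfm <- function(consensus, id = "TOY.1", name = "toy", weight = 10) {
    L <- nchar(consensus)
    m <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    b <- strsplit(consensus, "")[[1]]
    for (j in seq_len(L)) m[b[j], j] <- weight
    PFMatrix(id, name, m)
}

randomPfm <- function(L, id = "RND.1") {
    m <- matrix(stats::rpois(4 * L, 5) + stats::runif(4 * L), 4, L)
    PFMatrix(id, "random", m)
}

# naive per-base brute-force oracle for conserved CNVs over [1, regionLen]
cnvPerBaseOracle <- function(tracks, chrom, regionLen) {
    out <- GRanges()
    for (dir in c("AMP", "DEL")) {
        covered <- rep(TRUE, regionLen)
        for (t in tracks) {
            seg <- t[mcols(t)$direction == dir &
                         as.character(seqnames(t)) == chrom]
            hit <- rep(FALSE, regionLen)
            for (i in seq_along(seg)) {
                lo <- max(1L, start(seg)[i])
                hi <- min(regionLen, end(seg)[i])
                if (lo <= hi) hit[lo:hi] <- TRUE
            }
            covered <- covered & hit
        }
        if (any(covered)) {
            r <- rle(covered)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            keep <- r$values
            if (any(keep)) {
                gr <- GRanges(chrom, IRanges(starts[keep], ends[keep]),
                              direction = dir)
                out <- c(out, gr)
            }
        }
    }
    sort(out)
}

# naive PWM scan oracle: plain loops, own reverse complement
pwmScanOracle <- function(seq, pfm, pseudocount = 0.8, threshold = 0.8) {
    bg <- rep(0.25, 4)
    cn <- pfm@counts
    m <- log2(sweep(cn + pseudocount * bg, 2, colSums(cn) + pseudocount, "/") / bg)
    smin <- sum(apply(m, 2, min)); smax <- sum(apply(m, 2, max))
    L <- ncol(m)
    revcomp <- function(s)
        paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
    scoreAt <- function(s, k) {
        w <- strsplit(substr(s, k, k + L - 1), "")[[1]]
        idx <- match(w, c("A", "C", "G", "T"))
        if (any(is.na(idx))) return(NA_real_)
        sum(m[cbind(idx, seq_len(L))])
    }
    hits <- list()
    S <- nchar(seq)
    for (k in seq_len(S - L + 1)) {
        for (strand in c("+", "-")) {
            s <- if (strand == "+") seq else revcomp(seq)
            kk <- if (strand == "+") k else S - L + 2 - k
            raw <- scoreAt(s, kk)
            if (is.na(raw)) next
            rel <- if (smax > smin) (raw - smin) / (smax - smin) else 1
            if (rel >= threshold)
                hits[[length(hits) + 1]] <-
                    data.frame(offset = k - 1L, strand = strand,
                               rel_score = rel)
        }
    }
    if (!length(hits))
        return(data.frame(offset = integer(), strand = character(),
                          rel_score = numeric()))
    do.call(rbind, hits)
}
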