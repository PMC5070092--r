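#' @importFrom Biostrings DNAString reverseComplement
NULL

#' Convert a position frequency matrix to a log-odds weight matrix
#'
#' JASPAR-style conversion: each count cell becomes
#' `log2(((count + pseudocount * background_b) / (columnTotal + pseudocount))
#' / background_b)`, i.e. the pseudocount is distributed over bases in
#' proportion to the background. `scoreMin`/`scoreMax` are the sums of the
#' per-column minima/maxima, defining the relative score scale used by
#' [scanSequence()].
#'
#' @param pfm a [PFMatrix-class].
#' @param pseudocount total pseudocount per column (default 0.8).
#' @param background base composition (A,C,G,T), default uniform.
#' @return a [PWMatrix-class].
#' @examples
#' pfm <- PFMatrix("TOY.1", "toy", matrix(c(10, 0, 0, 0, 0, 10, 0, 0), 4,
#'                 dimnames = list(c("A", "C", "G", "T"), NULL)))
#' pfmToPwm(pfm)
#' @export
pfmToPwm <- function(pfm, pseudocount = 0.8, background = rep(0.25, 4)) {
    stopifnot(pseudocount > 0, length(background) == 4,
              abs(sum(background) - 1) < 1e-6)
    cn <- pfm@counts
    tot <- colSums(cn)
    if (any(tot <= 0)) abort("zero column total in motif ", pfm@matrixID)
    prob <- sweep(cn + pseudocount * background,
                  2, tot + pseudocount, "/")
    m <- log2(prob / background)
    rownames(m) <- DNA_BASES
    methods::new("PWMatrix", matrixID = pfm@matrixID, name = pfm@name,
                 matrix = m,
                 scoreMin = sum(apply(m, 2, min)),
                 scoreMax = sum(apply(m, 2, max)),
                 pseudocount = pseudocount, background = background)
}

# score every window of seq (character) against pwm; returns raw scores,
# NA at windows containing non-ACGT characters
pwmWindowScores <- function(seq, pwm) {
    L <- ncol(pwm@matrix)
    bases <- strsplit(toupper(seq), "")[[1]]
    S <- length(bases)
    if (S < L) return(numeric())
    code <- match(bases, DNA_BASES)  # NA for non-ACGT
    nWin <- S - L + 1L
    sc <- numeric(nWin)
    ok <- rep(TRUE, nWin)
    for (j in seq_len(L)) {
        cj <- code[j:(j + nWin - 1L)]
        bad <- is.na(cj)
        ok <- ok & !bad
        cj[bad] <- 1L
        sc <- sc + pwm@matrix[cbind(cj, j)]
    }
    sc[!ok] <- NA_real_
    sc
}

#' Scan a DNA sequence with a position weight matrix
#'
#' Scores every offset of the sequence (and of its reverse complement when
#' `bothStrands`) against the PWM and reports hits whose relative score
#' `(raw - scoreMin) / (scoreMax - scoreMin)` reaches `threshold`. Offsets
#' are 0-based positions of the match start on the forward strand for both
#' strands (a `-` hit at offset k covers the same bases as a `+` window at
#' k). Windows containing non-ACGT characters are skipped with a warning.
#'
#' @param seq DNA sequence (character scalar or `DNAString`).
#' @param pwm a [PWMatrix-class] from [pfmToPwm()].
#' @param threshold relative-score threshold in `[0, 1]` (default 0.80).
#' @param bothStrands also scan the reverse strand (default TRUE).
#' @return data.frame with columns `motif`, `offset`, `strand`, `score`,
#'   `rel_score`.
#' @export
scanSequence <- function(seq, pwm, threshold = 0.80, bothStrands = TRUE) {
    seq <- as.character(seq)
    L <- ncol(pwm@matrix)
    if (nchar(seq) < L)
        abort("sequence shorter than motif (", nchar(seq), " < ", L, ")")
    rng <- pwm@scoreMax - pwm@scoreMin
    rel <- function(raw) if (rng > 0) (raw - pwm@scoreMin) / rng else
        rep(1, length(raw))
    collect <- function(raw, strand) {
        if (!length(raw)) return(NULL)
        rs <- rel(raw)
        keep <- !is.na(rs) & rs >= threshold
        if (!any(keep)) return(NULL)
        off <- which(keep) - 1L
        if (strand == "-")  # mirror back to forward-strand coordinates
            off <- (nchar(seq) - L) - off
        data.frame(motif = pwm@matrixID, offset = off, strand = strand,
                   score = raw[keep], rel_score = rs[keep])
    }
    fwd <- pwmWindowScores(seq, pwm)
    if (any(is.na(fwd)))
        warning("skipped ", sum(is.na(fwd)),
                " window(s) containing non-ACGT characters")
    hits <- collect(fwd, "+")
    if (bothStrands) {
        rc <- as.character(reverseComplement(DNAString(gsub("[^ACGTacgt]", "N", seq))))
        hits <- rbind(hits, collect(pwmWindowScores(rc, pwm), "-"))
    }
    if (is.null(hits))
        return(data.frame(motif = character(), offset = integer(),
                          strand = character(), score = numeric(),
                          rel_score = numeric()))
    hits[order(hits$offset, hits$strand), , drop = FALSE]
}

#' Binding sites gained or lost between the X and Y allele of a SNP
#'
#' Substitutes each allele into the flanking sequence at the variant offset
#' and rescans; only windows overlapping the variant base are compared, so a
#' reported gain or loss is attributable to the SNP itself. For each motif:
#' `LOST_ON_Y` when the X-allele sequence has an overlapping hit at or above
#' threshold but the Y-allele sequence has none, `GAINED_ON_Y` for the
#' converse, `UNCHANGED` otherwise. Swapping the X and Y labels exchanges
#' LOST and GAINED.
#'
#' @param flank flanking DNA sequence (character).
#' @param variantOffset 0-based offset of the variant base within `flank`.
#' @param xAllele,yAllele the two alleles (single bases); at least one must
#'   differ from nothing — `xAllele == yAllele` is an error.
#' @param pwms list of [PWMatrix-class] objects (or a single one).
#' @param threshold relative-score threshold (default 0.80).
#' @return data.frame with one row per motif: `motif`, `name`, `status`,
#'   `best_rel_x`, `best_rel_y` (best overlapping relative scores, NA when no
#'   window overlaps).
#' @export
alleleDiff <- function(flank, variantOffset, xAllele, yAllele, pwms,
                       threshold = 0.80) {
    if (xAllele == yAllele) abort("xAllele and yAllele are identical: no variant")
    if (variantOffset < 0 || variantOffset >= nchar(flank))
        abort("variantOffset outside the flank")
    if (methods::is(pwms, "PWMatrix")) pwms <- list(pwms)
    sub <- function(allele) {
        s <- strsplit(flank, "")[[1]]
        s[variantOffset + 1L] <- allele
        paste(s, collapse = "")
    }
    seqX <- sub(xAllele)
    seqY <- sub(yAllele)
    rows <- lapply(pwms, function(pwm) {
        L <- ncol(pwm@matrix)
        # windows overlapping the variant base: offsets v-L+1 .. v
        inWin <- function(off) off >= variantOffset - L + 1L &
            off <= variantOffset
        bestOv <- function(seq) {
            h <- suppressWarnings(
                scanSequence(seq, pwm, threshold = 0, bothStrands = TRUE))
            h <- h[inWin(h$offset), , drop = FALSE]
            if (nrow(h)) max(h$rel_score) else NA_real_
        }
        bx <- bestOv(seqX)
        by <- bestOv(seqY)
        hitX <- !is.na(bx) && bx >= threshold
        hitY <- !is.na(by) && by >= threshold
        status <- if (hitX && !hitY) "LOST_ON_Y" else
            if (!hitX && hitY) "GAINED_ON_Y" else "UNCHANGED"
        data.frame(motif = pwm@matrixID, name = pwm@name, status = status,
                   best_rel_x = bx, best_rel_y = by)
    })
    do.call(rbind, rows)
}
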