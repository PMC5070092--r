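test_that("PFM to PWM conversion: degenerate, consensus and monotone cases", {
    # uniform PFM: every cell log2(1) = 0, score range collapses
    uni <- PFMatrix("U.1", "uniform", matrix(5, 4, 3))
    pwm <- pfmToPwm(uni)
    expect_true(all(pwm@matrix == 0))
    expect_equal(pwm@scoreMin, 0)
    expect_equal(pwm@scoreMax, 0)
    # one-hot motif: consensus attains scoreMax
    pwm2 <- pfmToPwm(onehotPfm("AC"))
    cons <- unname(pwm2@matrix["A", 1] + pwm2@matrix["C", 2])
    expect_equal(cons, pwm2@scoreMax)
    # increasing a base's count never decreases its cell score
    set.seed(20)
    for (i in 1:20) {
        pfm <- randomPfm(4)
        j <- sample(4, 1); b <- sample(4, 1)
        bumped <- pfm@counts; bumped[b, j] <- bumped[b, j] + 3
        p1 <- pfmToPwm(pfm)@matrix[b, j]
        p2 <- pfmToPwm(PFMatrix("RND.2", "r", bumped))@matrix[b, j]
        expect_gte(p2, p1)
    }
})

test_that("relative score is invariant under the affine score scale", {
    pwm <- pfmToPwm(randomPfm(3))
    hits <- scanSequence("ACGTACGTAC", pwm, threshold = 0)
    # shifting the raw matrix shifts raw scores but not relative scores
    shifted <- pwm
    shifted@matrix <- pwm@matrix + 1.7
    shifted@scoreMin <- pwm@scoreMin + 3 * 1.7
    shifted@scoreMax <- pwm@scoreMax + 3 * 1.7
    hits2 <- scanSequence("ACGTACGTAC", shifted, threshold = 0)
    expect_equal(hits$rel_score, hits2$rel_score)
})

test_that("consensus scores 1.0, anti-consensus 0.0", {
    pwm <- pfmToPwm(onehotPfm("ACGT"))
    hits <- scanSequence("ACGT", pwm, threshold = 0, bothStrands = FALSE)
    expect_equal(hits$rel_score, 1.0)
    # anti-consensus: a non-consensus base in every column
    anti <- scanSequence("CAAC", pwm, threshold = 0, bothStrands = FALSE)
    expect_equal(anti$rel_score, 0.0)
    # a full-threshold scan returns only the consensus window
    pwmNP <- pfmToPwm(onehotPfm("AACG"))  # non-palindromic
    strict <- scanSequence("TTAACGAA", pwmNP, threshold = 1)
    expect_equal(strict$offset, 2L)
    expect_equal(strict$strand, "+")
})

test_that("scan equals the brute-force oracle over offsets and strands", {
    set.seed(21)
    for (i in 1:20) {
        pfm <- randomPfm(sample(2:4, 1))
        seq <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
        got <- scanSequence(seq, pfmToPwm(pfm), threshold = 0.8)
        want <- pwmScanOracle(seq, pfm, threshold = 0.8)
        o <- order(want$offset, want$strand)
        expect_equal(got$offset, want$offset[o])
        expect_equal(got$strand, want$strand[o])
        expect_equal(got$rel_score, want$rel_score[o], tolerance = 1e-12)
    }
})

test_that("scan is exhaustive-oracle-equivalent over all 6-mers", {
    pfm <- PFMatrix("EX.1", "exhaust",
                    matrix(c(8, 1, 0, 3,
                             0, 5, 2, 1,
                             1, 1, 9, 0,
                             3, 0, 1, 8), 4, 4, byrow = TRUE))
    pwm <- pfmToPwm(pfm)
    bases <- c("A", "C", "G", "T")
    kmers <- do.call(paste0, expand.grid(bases, bases, bases,
                                         bases, bases, bases))
    nHits <- vapply(kmers, function(s)
        nrow(scanSequence(s, pwm, threshold = 0.85)), integer(1))
    oracle <- vapply(kmers, function(s)
        nrow(pwmScanOracle(s, pfm, threshold = 0.85)), integer(1))
    expect_equal(unname(nHits), unname(oracle))
    expect_gt(sum(nHits), 0)  # the check is not vacuous
})

test_that("reverse-complementing the sequence mirrors the strands", {
    pwm <- pfmToPwm(randomPfm(3))
    seq <- "ACGGTACGTTAC"
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    h1 <- scanSequence(seq, pwm, threshold = 0.7)
    h2 <- scanSequence(rc, pwm, threshold = 0.7)
    S <- nchar(seq); L <- 3
    mirrored <- data.frame(offset = S - L - h2$offset,
                           strand = ifelse(h2$strand == "+", "-", "+"),
                           rel_score = h2$rel_score)
    o1 <- order(h1$offset, h1$strand)
    o2 <- order(mirrored$offset, mirrored$strand)
    expect_equal(h1$offset[o1], mirrored$offset[o2])
    expect_equal(h1$strand[o1], mirrored$strand[o2])
    expect_equal(h1$rel_score[o1], mirrored$rel_score[o2])
})

test_that("non-ACGT positions are skipped with a warning", {
    pwm <- pfmToPwm(onehotPfm("AC"))
    expect_warning(hits <- scanSequence("ACNAC", pwm, threshold = 0),
                   "non-ACGT")
    expect_false(any(hits$offset %in% c(1L, 2L) & hits$strand == "+"))
})

test_that("allele substitution flips binding status as constructed", {
    # motif requires G at its 3rd column
    pwm <- pfmToPwm(onehotPfm("TAGC", id = "GATA.TOY", name = "gata-like"))
    flank <- "TTTTTAGCTTTT"           # consensus TAGC at offset 4..7
    # variant at the G (offset 6): X = G keeps the site, Y = T destroys it
    d <- alleleDiff(flank, 6L, "G", "T", pwm, threshold = 0.9)
    expect_equal(d$status, "LOST_ON_Y")
    expect_gte(d$best_rel_x, 0.9)
    expect_lt(d$best_rel_y, 0.9)
    # swapping the labels flips LOST <-> GAINED
    d2 <- alleleDiff(flank, 6L, "T", "G", pwm, threshold = 0.9)
    expect_equal(d2$status, "GAINED_ON_Y")
    # a substitution elsewhere leaves distant sites unchanged
    d3 <- alleleDiff("TAGCTTTTTTTT", 10L, "A", "C", pwm, threshold = 0.9)
    expect_equal(d3$status, "UNCHANGED")
    expect_error(alleleDiff(flank, 6L, "G", "G", pwm), "identical")
    expect_error(alleleDiff(flank, 50L, "G", "T", pwm), "outside")
})
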