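statsAt <- function(pos, sp = TRUE, chrom = "chr1") {
    GRanges(chrom, IRanges(pos, width = 1), sex_patterned = sp,
            fst = runif(length(pos)))
}

test_that("window boundaries follow the 0-anchored half-open convention", {
    st <- statsAt(c(10000, 10001))
    w <- windowCounts(st, chromLengths = c(chr1 = 30000))
    expect_equal(length(w), 3L)
    expect_equal(mcols(w)$n_sex_patterned, c(1L, 1L, 0L))
    expect_equal(start(w), c(1L, 10001L, 20001L))
    # trailing partial window kept with its true length
    w2 <- windowCounts(statsAt(5), chromLengths = c(chr1 = 25000))
    expect_equal(width(w2)[3], 5000L)
    expect_error(windowCounts(st, windowSize = 0), "positive")
})

test_that("window counts conserve totals and respect gaps", {
    set.seed(7)
    pos <- sample.int(100000, 25)
    st <- statsAt(pos, sp = rep(c(TRUE, FALSE), length.out = 25))
    w <- windowCounts(st, chromLengths = c(chr1 = 100000))
    expect_equal(sum(mcols(w)$n_total_snps), 25L)
    expect_equal(sum(mcols(w)$n_sex_patterned), 13L)
    # brute-force recount per window
    brute <- vapply(seq_along(w), function(i)
        sum(pos >= start(w)[i] & pos <= end(w)[i]), integer(1))
    expect_equal(mcols(w)$n_total_snps, brute)
    gaps <- GRanges("chr1", IRanges(1, 2500))
    wg <- windowCounts(st, gaps = gaps, chromLengths = c(chr1 = 100000))
    expect_equal(mcols(wg)$effective_len[1], 7500L)
    expect_equal(mcols(wg)$effective_len[2], 10000L)
})

test_that("enrichment threshold is inclusive and monotone", {
    w <- windowCounts(statsAt(c(1:10, 10001:10009, 20001)),
                      chromLengths = c(chr1 = 30000))
    w <- callEnriched(w)
    expect_equal(mcols(w)$enriched, c(TRUE, FALSE, FALSE))  # 10 / 9 / 1
    for (k in c(1, 5, 12)) {
        nk <- sum(mcols(callEnriched(w, k))$enriched)
        nk1 <- sum(mcols(callEnriched(w, k + 1))$enriched)
        expect_gte(nk, nk1)
    }
})

test_that("region summaries compute densities and mean FST over defined sites", {
    st <- GRanges("chr1", IRanges(c(100, 200, 300, 15000), width = 1),
                  sex_patterned = c(TRUE, TRUE, FALSE, FALSE),
                  fst = c(0.5, NA, 0.1, 0.3))
    w <- callEnriched(windowCounts(st, chromLengths = c(chr1 = 20000)), 2)
    s <- summarizeRegion(st, w, GRanges("chr1", IRanges(1, 10000)), "r1")
    expect_equal(s$n_sex_patterned, 2L)
    expect_equal(s$density_per_mb, 2 / 0.01)
    expect_equal(s$mean_fst_polymorphic, mean(c(0.5, 0.1)))  # NA excluded
    expect_equal(s$n_enriched_windows, 1L)
    expect_error(summarizeRegion(st, w, GRanges(), "r0"), "zero-length")
    # no sites: zero density, undefined mean FST
    s2 <- summarizeRegion(st[0], w, GRanges("chr1", IRanges(1, 10000)), "r")
    expect_equal(s2$n_sex_patterned, 0L)
    expect_true(is.na(s2$mean_fst_polymorphic))
})

test_that("Mann-Whitney U: exact enumeration, ties, and invariances", {
    m <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
    expect_equal(m$U, 0)
    expect_equal(m$p.value, 0.1)  # 2/20 arrangements as extreme
    # identical samples: U = n_a n_b / 2, p ~ 1
    m2 <- mannWhitneyU(rep(1:4, 2), rep(1:4, 2))
    expect_equal(m2$U, 32)
    expect_gt(m2$p.value, 0.95)
    expect_error(mannWhitneyU(numeric(), 1:3), "non-empty")
    set.seed(8)
    for (i in 1:20) {
        a <- sample.int(1000, 8)
        b <- sample(setdiff(seq_len(2000), a), 8) + 0.5  # untied by construction
        m <- mannWhitneyU(a, b)
        # swap symmetry and shift invariance of the two-sided p
        expect_equal(mannWhitneyU(b, a)$p.value, m$p.value)
        expect_equal(mannWhitneyU(a + 17, b + 17)$p.value, m$p.value)
        # independent oracle: wilcox.test exact p for untied samples
        expect_equal(m$p.value,
                     wilcox.test(a, b, exact = TRUE)$p.value)
        expect_equal(m$U, unname(wilcox.test(a, b)$statistic))
    }
})

test_that("normal approximation tracks the exact p for moderate samples", {
    set.seed(9)
    for (i in 1:10) {
        a <- sample.int(10000, 8); b <- sample.int(10000, 8)
        exact <- mannWhitneyU(a, b)$p.value
        # force the approximate path by exceeding the enumeration cutoff
        a2 <- c(a, max(a, b) + 1); b2 <- c(b, max(a, b) + 2)
        approxP <- mannWhitneyU(a2, b2)$p.value
        exact2 <- wilcox.test(a2, b2, exact = TRUE)$p.value
        expect_lt(abs(approxP - exact2), 0.02)
    }
})

test_that("Bonferroni threshold reproduces the printed alpha", {
    expect_equal(bonferroniAlpha(0.05, 12), 0.004167)
    expect_equal(bonferroniAlpha(0.05, 1), 0.05)
    expect_equal(bonferroniAlpha(0.01, 4), 0.0025)
    expect_error(bonferroniAlpha(0.05, 0), "m must be")
})

test_that("region comparisons flag simulated enrichment and keep type I error", {
    cfg <- simConfig(c(chr1 = 1e6), sdRegion = GRanges("chr1:1-300000"),
                     sdSnpRate = 1e-3, backgroundSnpRate = 5e-5, seed = 21)
    sim <- simulatePools(cfg)
    st <- scanSites(sim$counts, quiet = TRUE)
    w <- callEnriched(windowCounts(st, chromLengths = c(chr1 = 1e6)))
    sd <- GRanges("chr1", IRanges(1, 300000))
    rest <- GRanges("chr1", IRanges(300001, 1e6))
    cmp <- compareRegions(w, list(list(label_a = "sd", region_a = sd,
                                       label_b = "rest", region_b = rest)))
    expect_true(cmp$significant)
    expect_lt(cmp$p, bonferroniAlpha())
    # null: two disjoint halves of a background-only simulation
    for (seed in 1:3) {
        cfg0 <- simConfig(c(chr1 = 1e6), backgroundSnpRate = 5e-4,
                          seed = seed)
        st0 <- scanSites(simulatePools(cfg0)$counts, quiet = TRUE)
        w0 <- callEnriched(windowCounts(st0, chromLengths = c(chr1 = 1e6)))
        cmp0 <- compareRegions(
            w0, list(list(label_a = "h1",
                          region_a = GRanges("chr1", IRanges(1, 5e5)),
                          label_b = "h2",
                          region_b = GRanges("chr1", IRanges(5e5 + 1, 1e6)))),
            value = "n_total_snps")
        expect_false(cmp0$significant)
    }
    expect_equal(nrow(compareRegions(w, list())), 0L)
    expect_error(compareRegions(w, list(list(
        label_a = "a", region_a = sd, label_b = "b", region_b = sd))),
        "disjoint")
})
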