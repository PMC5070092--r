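sdCfg <- function(seed = 11, ...) {
    simConfig(c(chr1 = 2e5), sdRegion = GRanges("chr1:1-100000"),
              sdSnpRate = 1e-3, backgroundSnpRate = 5e-4, seed = seed, ...)
}

test_that("the simulator is deterministic under a fixed seed", {
    s1 <- simulatePools(sdCfg())
    s2 <- simulatePools(sdCfg())
    expect_identical(s1$truth, s2$truth)
    expect_identical(assays(s1$counts), assays(s2$counts))
    f1 <- tempfile(); f2 <- tempfile()
    writeSyncTable(s1$counts, f1)
    writeSyncTable(s2$counts, f2)
    expect_identical(readLines(f1), readLines(f2))
    s3 <- simulatePools(sdCfg(seed = 12))
    expect_false(identical(s1$truth$pos, s3$truth$pos))
})

test_that("zero rates give zero sites; empty SD region with a rate errors", {
    cfg <- simConfig(c(chr1 = 1e5), seed = 1)
    expect_equal(nrow(simulatePools(cfg)$truth), 0L)
    expect_error(simConfig(c(chr1 = 1e5), sdSnpRate = 0.001, seed = 1),
                 "sdRegion")
})

test_that("truth frequencies sit on the chromosome-count grid", {
    sim <- simulatePools(sdCfg())
    tr <- sim$truth
    sp <- tr[tr$category == "sex_patterned_Y", ]
    # male pool Y frequency exactly 0.5 = nMales/(2 nMales); female pool 0
    yHet <- ifelse(sp$alt == sp$y_allele, sp$p_het_alt, 1 - sp$p_het_alt)
    yHom <- ifelse(sp$alt == sp$y_allele, sp$p_hom_alt, 1 - sp$p_hom_alt)
    expect_true(all(yHet == 0.5))
    expect_true(all(yHom == 0))
    bg <- tr[tr$category == "background", ]
    expect_true(all(bg$p_het_alt == bg$p_hom_alt))
    expect_true(all(bg$p_het_alt %in% seq(0.1, 0.9, by = 0.1)))
    # every emitted site appears exactly once in the truth table
    expect_equal(anyDuplicated(paste(tr$chrom, tr$pos)), 0L)
    expect_setequal(paste(tr$chrom, tr$pos),
                    paste(seqnames(rowRanges(sim$counts)),
                          start(rowRanges(sim$counts))))
})

test_that("male-pool alt fraction at sex-patterned sites is binomial around 0.5", {
    # ~10,000 sex-patterned sites at coverage 1000: the mean alt-read
    # fraction of the Y allele estimates 0.5 with SE ~ sqrt(0.25/1000/n)
    cfg <- simConfig(c(chr1 = 1e5), sdRegion = GRanges("chr1:1-100000"),
                     sdSnpRate = 0.1, meanCoverage = 1000, seed = 5)
    sim <- simulatePools(cfg)
    tr <- sim$truth
    cnt <- sim$counts
    yIsAlt <- tr$alt == tr$y_allele
    frac <- ifelse(yIsAlt,
                   altCounts(cnt)[, "het"], refCounts(cnt)[, "het"]) /
        poolDepth(cnt)[, "het"]
    expect_gt(nrow(tr), 9000)
    expect_equal(mean(frac), 0.5, tolerance = 0.01)
})

test_that("detector recall rises monotonically with coverage", {
    recallAt <- function(cov) {
        cfg <- simConfig(c(chr1 = 1e6), sdRegion = GRanges("chr1:1-1000000"),
                         sdSnpRate = 2e-3, meanCoverage = cov, seed = 42)
        sim <- simulatePools(cfg)
        st <- scanSites(sim$counts, quiet = TRUE)
        truthPos <- sim$truth$pos[sim$truth$category == "sex_patterned_Y"]
        detPos <- start(st)[mcols(st)$sex_patterned]
        mean(truthPos %in% detPos)
    }
    r <- vapply(c(10, 35, 100), recallAt, numeric(1))
    # allow 2 points of sampling tolerance on the monotone trend
    expect_gte(r[2], r[1] - 0.02)
    expect_gte(r[3], r[2] - 0.02)
    expect_gt(r[3], 0.95)
})

test_that("species-pair truth follows the stated allocation rules", {
    mkCfg <- function(seed) sdCfg(seed = seed)
    # sharedFraction = 0 -> empty intersection of sex-patterned truth
    pr0 <- simulateSpeciesPair(mkCfg(1), mkCfg(2), sharedFraction = 0,
                               seed = 9)
    expect_equal(nrow(pr0$shared_truth), 0L)
    spA <- pr0$a$truth[pr0$a$truth$category == "sex_patterned_Y", ]
    spB <- pr0$b$truth[pr0$b$truth$category == "sex_patterned_Y", ]
    expect_length(intersect(paste(spA$chrom, spA$pos),
                            paste(spB$chrom, spB$pos)), 0L)
    # deterministic rounding of the class allocation
    pr <- simulateSpeciesPair(mkCfg(1), mkCfg(2), sharedFraction = 0.5,
                              switchFraction = 0.25, yReplaceFraction = 0.25,
                              seed = 9)
    nCand <- sum(spA$pos >= 1 & spA$pos <= 1e5)  # same seed as pr0 species A
    nShared <- nrow(pr$shared_truth)
    expect_equal(nShared, round(nCand * 0.5))
    tab <- table(pr$shared_truth$class)
    expect_equal(unname(tab["SWITCHED"]), round(nShared * 0.25))
    expect_equal(unname(tab["SAME_X_DIFF_Y"]), round(nShared * 0.25))
    expect_equal(unname(tab["CONSERVED"]),
                 nShared - 2 * round(nShared * 0.25))
    # allele bookkeeping per class
    st <- pr$shared_truth
    expect_true(all(st$x_b[st$class == "CONSERVED"] ==
                        st$x_a[st$class == "CONSERVED"]))
    expect_true(all(st$x_b[st$class == "SWITCHED"] ==
                        st$y_a[st$class == "SWITCHED"]))
    expect_true(all(st$y_b[st$class == "SAME_X_DIFF_Y"] !=
                        st$y_a[st$class == "SAME_X_DIFF_Y"]))
    expect_error(simulateSpeciesPair(
        mkCfg(1),
        simConfig(c(chr1 = 2e5), sdRegion = GRanges("chr1:150001-200000"),
                  sdSnpRate = 1e-3, seed = 2),
        sharedFraction = 0.5), "overlap")
})

test_that("simulated CNV tracks reproduce truth when noiseless", {
    true <- GRanges("chr1", IRanges(c(1001, 5001), c(1800, 5900)),
                    direction = c("AMP", "DEL"))
    sim <- simulateCnvTracks(3, true, noiseRate = 0, jitter = 0, seed = 2)
    expect_length(sim$tracks, 3L)
    for (t in sim$tracks) {
        expect_equal(start(t), start(true))
        expect_equal(end(t), end(true))
        lr <- mcols(t)$log2_ratio
        expect_true(all(abs(lr) >= 0.2))
        expect_equal(sign(lr), c(1, -1))
    }
    sim2 <- simulateCnvTracks(3, true, noiseRate = 0, jitter = 0, seed = 2)
    expect_identical(sim$tracks, sim2$tracks)
    # conserved detector recovers exactly the true intervals at jitter 0
    called <- conservedCnvs(lapply(sim$tracks, thresholdSegments))
    expect_equal(granges(called), granges(true), ignore_attr = TRUE)
    # noise segments stay private to single tracks
    simN <- simulateCnvTracks(3, true, noiseRate = 4, jitter = 0, seed = 3)
    calledN <- conservedCnvs(lapply(simN$tracks, thresholdSegments))
    expect_equal(granges(calledN), granges(true), ignore_attr = TRUE)
})
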