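test_that("aberrance gating uses either channel with its threshold", {
    cfg <- ccConfig()
    expect_false(isAberrant(0.0, 0.50, cfg))
    expect_true(isAberrant(0.0, 0.80, cfg))   # cnLOH at f = 0.6
    expect_true(isAberrant(-0.51, NA, cfg))   # log2R channel alone
    expect_false(isAberrant(0.1, NA, cfg))
    expect_equal(isAberrant(c(0, 0.2), c(0.8, NA), cfg), c(TRUE, TRUE))
})

test_that("zero-noise segments are fitted to their generating state", {
    # hemizygous deletion at f = 0.6
    fit <- fitSegment(expectedLog2R(0.6, 1), 1 - expectedBAF(0.6, 1, 0))
    expect_equal(fit$n_total, 1L)
    expect_equal(fit$n_minor, 0L)
    expect_equal(fit$f, 0.6)
    # cnLOH at f = 0.4: med_log2r 0, expected BAF 0.3 so mBAF 0.7
    expect_equal(expectedBAF(0.4, 2, 0), 0.3)
    fit2 <- fitSegment(0, 0.7)
    expect_equal(fit2$n_total, 2L)
    expect_equal(fit2$n_minor, 0L)
    expect_equal(fit2$f, 0.4)
    # a normal segment never reaches fitting
    ss <- segmentSet("1", 1e6, 50e6, 1000L, 0, 0.5, genomeBp = 1e9)
    fits <- fitSegments(ss)
    expect_false(fits$aberrant[1])
    expect_true(is.na(fits$f[1]))
})

test_that("fitSegment agrees exactly with the brute-force grid oracle", {
    cfg <- ccConfig()
    set.seed(31)
    states <- expand.grid(nT = 0:4, nB = 0:2)
    states <- states[states$nB <= states$nT %/% 2 &
                         !(states$nT == 2 & states$nB == 1), ]
    for (i in 1:100) {
        s <- states[sample(nrow(states), 1), ]
        f <- sample(seq(0.05, 1, by = 0.01), 1)
        if (s$nT == 0 && f >= 1) f <- 0.5
        ml <- expectedLog2R(f, s$nT)
        eb <- expectedBAF(f, s$nT, s$nB)
        mb <- if (runif(1) < 0.8) 0.5 + abs(eb - 0.5) else NA_real_
        got <- fitSegment(ml, mb, cfg)
        want <- oracleFitSegment(ml, mb)
        expect_equal(got$n_total, want$nT)
        expect_equal(got$n_minor, want$nB)
        expect_equal(got$f, want$f)
    }
})

test_that("fraction clustering matches the spec example and the partition oracle", {
    fits <- data.frame(f = c(0.60, 0.58, 0.25),
                       length_bp = c(3e7, 3e7, 3e7),
                       chrom = c("1", "2", "3"), start = 1e6)
    cl <- clusterFractions(fits, ccConfig())
    expect_equal(nrow(cl$clusters), 2L)
    expect_equal(cl$clusters$centroid_f, c(0.59, 0.25), tolerance = 1e-9)
    oracle <- oracleClusterPartitions(fits$f, fits$length_bp, 0.08)
    expect_equal(length(oracle), 2L)
    expect_equal(sort(cl$clusters$centroid_f), sort(oracle), tolerance = 1e-9)

    # empty input
    empty <- clusterFractions(NULL, ccConfig())
    expect_equal(nrow(empty$clusters), 0L)
    # identical fractions collapse to one cluster conserving footprint
    same <- data.frame(f = rep(0.4, 5), length_bp = rep(1e7, 5),
                       chrom = as.character(1:5), start = 1e6)
    cs <- clusterFractions(same, ccConfig())
    expect_equal(nrow(cs$clusters), 1L)
    expect_equal(cs$clusters$footprint_bp, 5e7)
})

test_that("clustering is invariant to input row order", {
    set.seed(13)
    fits <- data.frame(f = round(runif(12, 0.05, 0.95), 2),
                       length_bp = sample(1:9, 12, TRUE) * 1e7,
                       chrom = as.character(sample(1:22, 12)),
                       start = sample(1e6:9e7, 12))
    cl1 <- clusterFractions(fits, ccConfig())
    for (r in 1:5) {
        perm <- fits[sample(nrow(fits)), ]
        cl2 <- clusterFractions(perm, ccConfig())
        expect_equal(cl1$clusters, cl2$clusters, tolerance = 1e-12)
    }
})

test_that("CC counting applies the footprint rule and Mono classification", {
    genome <- sum(autosomeLengths())
    # no aberrant segments: CC = 0, Mono
    ssN <- segmentSet("1", 1e6, 30e6, 2000L, 0, 0.5, genomeBp = genome)
    resN <- computeCC(ssN)
    expect_equal(ccNumber(resN), 0L)
    expect_equal(ccClass(resN), "Mono")

    # two clusters above the footprint: CC = 2, Poly
    ss2 <- exactSegmentSet(c(0.6, 0.25), c(1L, 1L), c(0L, 0L), c(0.03, 0.02))
    res2 <- computeCC(ss2)
    expect_equal(ccNumber(res2), 2L)
    expect_equal(ccClass(res2), "Poly")
    expect_equal(sum(ccClusters(res2)$pass), 2L)

    # genomeBp must be positive
    ssZ <- new("SegmentSet", ranges = GenomicRanges::GRanges(),
               genomeBp = 0, sampleId = "z")
    expect_error(computeCC(ssZ), "genomeBp")
})

test_that("a 0.8% cluster appears only at the 0.5% footprint", {
    # main clone at f = 0.6 spanning 3%, second cluster at f = 0.3
    # spanning 0.8% of the genome
    ss <- exactSegmentSet(c(0.6, 0.3), c(1L, 1L), c(0L, 0L), c(0.03, 0.008))
    res1 <- computeCC(ss, ccConfig(footprint_fraction = 0.01))
    res05 <- computeCC(ss, ccConfig(footprint_fraction = 0.005))
    expect_equal(ccNumber(res1), 1L)
    expect_equal(ccNumber(res05), 2L)
    cl <- ccClusters(res1)
    expect_equal(sum(!cl$pass), 1L)
    expect_equal(cl$footprint_fraction[!cl$pass], 0.008, tolerance = 1e-6)
})

test_that("relabeling chromosomes never changes the CC number", {
    ss <- exactSegmentSet(c(0.6, 0.25, 0.6), c(1L, 1L, 2L), c(0L, 0L, 0L),
                          c(0.02, 0.02, 0.015), chrom = c("1", "2", "3"))
    ssRe <- exactSegmentSet(c(0.6, 0.25, 0.6), c(1L, 1L, 2L), c(0L, 0L, 0L),
                            c(0.02, 0.02, 0.015), chrom = c("20", "9", "4"))
    expect_equal(ccNumber(computeCC(ss)), ccNumber(computeCC(ssRe)))
})

test_that("CC equals zero iff no cluster passes or nothing is aberrant", {
    # aberrant but sub-footprint
    ssSub <- exactSegmentSet(0.5, 1L, 0L, 0.005)
    res <- computeCC(ssSub)
    expect_equal(ccNumber(res), 0L)
    expect_equal(ccClass(res), "Mono")
    expect_equal(nrow(ccClusters(res)), 1L)
    expect_false(any(ccClusters(res)$pass))
})
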