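delArch <- function(f = 0.6) clonalArchitecture(f,
    data.frame(clone_id = "c1", ccf = 1),
    data.frame(chrom = "4", start = 30e6, end = 60e6 - 1,
               n_total = 1L, n_minor = 0L, clone_id = "c1"))

test_that("informative-probe selection keeps the heterozygous-like window", {
    ps <- probeSet(rep("1", 4), 1:4 * 1e6, rep(0, 4),
                   c(0.98, 0.50, 0.03, 0.001))
    kept <- selectInformative(ps)
    expect_equal(S4Vectors::mcols(probeRanges(kept))$baf, c(0.50, 0.03))
    # zero-noise het BAF under a 90% deletion is still informative
    b <- expectedBAF(0.9, 1, 0)
    expect_equal(b, (1 - 0.9) / (2 - 0.9), tolerance = 1e-10)
    expect_gte(b, 0.03)
})

test_that("a homogeneous zero-noise genome yields one segment per chromosome", {
    arch <- clonalArchitecture(0.7, data.frame(clone_id = "c1", ccf = 1))
    sim <- simulateSample(arch, exactNoiseModel(nProbes = 20000L), seed = 8)
    seg <- segmentGenome(sim$probes)
    expect_equal(length(seg), 22L)
    expect_equal(sort(as.character(GenomicRanges::seqnames(segmentRanges(seg)))),
                 sort(as.character(1:22)))
})

test_that("a zero-noise deletion is cut into three segments with exact medians", {
    sim <- simulateSample(delArch(0.6), exactNoiseModel(nProbes = 30000L),
                          seed = 9)
    seg <- segmentGenome(sim$probes)
    gr <- segmentRanges(seg)
    on4 <- gr[as.character(GenomicRanges::seqnames(gr)) == "4"]
    expect_equal(length(on4), 3L)
    mid <- on4[2]
    expect_equal(S4Vectors::mcols(mid)$medLog2R, -0.51457, tolerance = 1e-4)
    expect_equal(S4Vectors::mcols(mid)$medMBAF, 1 - 0.28571, tolerance = 1e-4)
    expect_equal(S4Vectors::mcols(on4)$medLog2R[c(1, 3)], c(0, 0))

    # breakpoints land within one probe spacing of the injected bounds
    pg <- probeRanges(sim$probes)
    pos4 <- GenomicRanges::start(pg[as.character(GenomicRanges::seqnames(pg)) == "4"])
    spacing <- max(diff(pos4))
    expect_lt(abs(GenomicRanges::start(mid) - 30e6), spacing + 1)
    expect_lt(abs(GenomicRanges::end(mid) - 60e6), spacing + 1)
})

test_that("emitted segments tile without overlap and never share probes", {
    sim <- simulateSample(archWithFractions(c(0.6, 0.3)),
                          noiseModel(nProbes = 20000L), seed = 10)
    seg <- segmentGenome(sim$probes)
    gr <- segmentRanges(seg)
    hits <- GenomicRanges::findOverlaps(gr, gr)
    expect_true(all(S4Vectors::queryHits(hits) == S4Vectors::subjectHits(hits)))
    pg <- probeRanges(sim$probes)
    cov <- GenomicRanges::findOverlaps(pg, gr)
    expect_lte(max(table(S4Vectors::queryHits(cov))), 1)
    expect_gte(genomeBp(seg), sum(as.numeric(GenomicRanges::width(gr))))
})

test_that("appending homozygous probes does not change zero-noise segmentation", {
    sim <- simulateSample(delArch(0.6), exactNoiseModel(nProbes = 15000L),
                          seed = 12)
    seg1 <- segmentGenome(sim$probes)
    gr <- probeRanges(sim$probes)
    # interleave extra homozygous probes carrying the same exact log2r
    chrom <- as.character(GenomicRanges::seqnames(gr))
    pos <- GenomicRanges::start(gr)
    l2r <- S4Vectors::mcols(gr)$log2r
    extraIdx <- seq(1, length(pos) - 1, by = 7)
    exPos <- pos[extraIdx] + 1L
    keep <- exPos < pos[extraIdx + 1]
    ps2 <- probeSet(c(chrom, chrom[extraIdx][keep]),
                    c(pos, exPos[keep]),
                    c(l2r, l2r[extraIdx][keep]),
                    c(S4Vectors::mcols(gr)$baf, rep(0.98, sum(keep))))
    seg2 <- segmentGenome(ps2)
    m1 <- S4Vectors::mcols(segmentRanges(seg1))
    m2 <- S4Vectors::mcols(segmentRanges(seg2))
    expect_equal(length(seg1), length(seg2))
    expect_equal(m1$medLog2R, m2$medLog2R, tolerance = 1e-8)
    expect_equal(m1$medMBAF, m2$medMBAF, tolerance = 1e-8)
})

test_that("doubling log2R noise does not inflate segment counts on null genomes", {
    arch <- clonalArchitecture(0.7, data.frame(clone_id = "c1", ccf = 1))
    counts <- sapply(1:5, function(s) {
        n1 <- length(segmentGenome(simulateSample(arch,
            noiseModel(sigmaLog2R = 0.25, nProbes = 10000L), seed = s)$probes))
        n2 <- length(segmentGenome(simulateSample(arch,
            noiseModel(sigmaLog2R = 0.5, nProbes = 10000L), seed = s)$probes))
        c(n1, n2)
    })
    expect_lte(sum(counts[2, ]), sum(counts[1, ]))
})

test_that("too few probes gives an empty SegmentSet with a warning", {
    ps <- probeSet(rep("1", 10), 1:10 * 1e6, rnorm(10, 0, 0.1), runif(10))
    expect_warning(seg <- segmentGenome(ps), "too few")
    expect_equal(length(seg), 0L)
})
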