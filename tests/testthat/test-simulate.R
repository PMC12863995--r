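test_that("simulator output is deterministic given the seed", {
    arch <- archWithFractions(c(0.6, 0.3))
    s1 <- simulateSample(arch, noiseModel(nProbes = 2000L), seed = 99)
    s2 <- simulateSample(arch, noiseModel(nProbes = 2000L), seed = 99)
    expect_identical(S4Vectors::mcols(probeRanges(s1$probes)),
                     S4Vectors::mcols(probeRanges(s2$probes)))
    expect_identical(GenomicRanges::start(probeRanges(s1$probes)),
                     GenomicRanges::start(probeRanges(s2$probes)))
    s3 <- simulateSample(arch, noiseModel(nProbes = 2000L), seed = 100)
    expect_false(identical(S4Vectors::mcols(probeRanges(s1$probes)),
                           S4Vectors::mcols(probeRanges(s3$probes))))
})

test_that("event-free architecture renders a flat genome with truth CC 0", {
    arch <- clonalArchitecture(0.7, data.frame(clone_id = "c1", ccf = 1))
    sim <- simulateSample(arch, exactNoiseModel(nProbes = 5000L), seed = 3)
    gr <- probeRanges(sim$probes)
    expect_true(all(S4Vectors::mcols(gr)$log2r == 0))
    b <- S4Vectors::mcols(gr)$baf
    het <- b > 0.1 & b < 0.9
    expect_true(all(b[het] == 0.5))
    expect_true(all(b[!het] %in% c(0.02, 0.98)))
    expect_equal(sim$truth$expected_cc, 0L)
})

test_that("zero-noise deletion probes sit at their closed-form expectations", {
    arch <- clonalArchitecture(0.6, data.frame(clone_id = "c1", ccf = 1),
        data.frame(chrom = "4", start = 1e6, end = 31e6,
                   n_total = 1L, n_minor = 0L, clone_id = "c1"))
    sim <- simulateSample(arch, exactNoiseModel(nProbes = 50000L), seed = 5)
    gr <- probeRanges(sim$probes)
    inEvent <- as.character(GenomicRanges::seqnames(gr)) == "4" &
        GenomicRanges::start(gr) >= 1e6 & GenomicRanges::start(gr) <= 31e6
    l <- S4Vectors::mcols(gr)$log2r[inEvent]
    expect_equal(median(l), log2(1.4 / 2), tolerance = 1e-6)
    expect_equal(median(l), -0.51457, tolerance = 1e-5)
    b <- S4Vectors::mcols(gr)$baf[inEvent]
    het <- b > 0.1 & b < 0.9
    expect_equal(sort(unique(round(b[het], 5))),
                 round(c(0.4 / 1.4, 1 - 0.4 / 1.4), 5))
})

test_that("truth record counts distinct fractions passing the footprint", {
    # two clones with >= 2% footprints each
    arch <- archWithFractions(c(0.6, 0.25), mb = 35)
    sim <- simulateSample(arch, noiseModel(nProbes = 1000L), seed = 1,
                          footprint = 0.01)
    expect_equal(sim$truth$expected_cc, 2L)
    # sub-footprint clone is not counted
    small <- clonalArchitecture(0.5,
        data.frame(clone_id = "c1", ccf = 1),
        data.frame(chrom = "1", start = 1e6, end = 1e6 + 15.5e6,
                   n_total = 1L, n_minor = 0L, clone_id = "c1"))
    simS <- simulateSample(small, noiseModel(nProbes = 1000L), seed = 1,
                           footprint = 0.01)
    expect_equal(simS$truth$expected_cc, 0L)
    expect_equal(simulateSample(small, noiseModel(nProbes = 1000L), seed = 1,
                                footprint = 0.005)$truth$expected_cc, 1L)
})

test_that("overlapping events of distinct clones are rejected unless nested", {
    clones <- data.frame(clone_id = c("a", "b"), ccf = c(1, 0.5))
    ev <- data.frame(chrom = "1", start = c(1e6, 5e6), end = c(10e6, 15e6),
                     n_total = c(3L, 1L), n_minor = c(1L, 0L),
                     clone_id = c("a", "b"))
    expect_error(clonalArchitecture(0.8, clones, ev), "overlap")
    expect_s4_class(clonalArchitecture(0.8, clones, ev, nested = TRUE),
                    "ClonalArchitecture")
})

test_that("cohort simulator honors the null and degenerate cases", {
    # HR = 1: event rates agree within binomial noise
    coh <- simulateCohort(1000, hazardRatio = 1, seed = 2)
    cl <- coh$clinical
    r <- tapply(cl$efs_event, cl$cc_class, mean)
    expect_lt(abs(r["Mono"] - r["Poly"]), 0.08)
    # near-immediate censoring: KM stays at 1
    cohC <- simulateCohort(200, censoring = c(1e-4, 1e-4), seed = 3)
    km <- kmEstimate(cohC$clinical$efs_days, cohC$clinical$efs_event)
    expect_equal(survivalAt(km, 10), 1)
    expect_error(simulateCohort(100, censoring = c(5, 1)), "censoring")
})

test_that("cohort files written to disk are readable by the io module", {
    d <- tempfile()
    coh <- simulateCohort(8, seed = 4, dir = d, renderProbes = TRUE,
                          noise = noiseModel(nProbes = 500L))
    df <- readClinicalCsv(file.path(d, "clinical.csv"))
    expect_equal(nrow(df), 8L)
    expect_equal(sum(df$efs_event), sum(coh$clinical$efs_event))
    tsv <- file.path(d, paste0(df$patient_id[1], ".tsv"))
    expect_true(file.exists(tsv))
    expect_s4_class(readProbeTable(tsv), "ProbeSet")
    unlink(d, recursive = TRUE)
})
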