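# Small fixture builders shared across test files.

# single-clone architecture: one hemizygous deletion + one cnLOH event
# per clone, each `mb` megabases, well separated across chromosomes
archWithFractions <- function(fractions, purity = max(fractions), mb = 35) {
    stopifnot(length(fractions) <= 3, all(fractions <= purity))
    clones <- data.frame(clone_id = paste0("c", seq_along(fractions)),
                         ccf = fractions / purity)
    span <- mb * 1e6
    events <- do.call(rbind, lapply(seq_along(fractions), function(k)
        data.frame(chrom = as.character(c(2 * k - 1, 2 * k)),
                   start = 1e7, end = 1e7 + span - 1,
                   n_total = c(1L, 2L), n_minor = c(0L, 0L),
                   clone_id = paste0("c", k))))
    clonalArchitecture(purity, clones, events)
}

# random architecture for property tests: 0-3 clones at well separated
# fractions, deletion + cnLOH events per clone
randomArch <- function() {
    k <- sample(0:3, 1)
    if (k == 0) return(architectureForCC(0))
    f <- sort(sample(seq(0.25, 0.9, by = 0.05), k), decreasing = TRUE)
    while (k > 1 && min(-diff(f)) < 0.18)
        f <- sort(sample(seq(0.25, 0.9, by = 0.05), k), decreasing = TRUE)
    archWithFractions(f, purity = max(f), mb = sample(25:45, 1))
}

# SegmentSet built directly from (f, state) ground truth at exact
# expectations; spans in fraction of the genome
exactSegmentSet <- function(f, nT, nB, spanFrac, genome = sum(autosomeLengths()),
                            chrom = NULL) {
    n <- length(f)
    if (is.null(chrom)) chrom <- as.character(seq_len(n))
    spanBp <- round(spanFrac * genome)
    ml <- expectedLog2R(f, nT)
    mb <- vapply(seq_len(n), function(i) {
        eb <- expectedBAF(f[i], nT[i], nB[i])
        0.5 + abs(eb - 0.5)
    }, 0)
    segmentSet(chrom, start = rep(1e6, n), end = 1e6 + spanBp - 1,
               numProbes = pmax(50L, as.integer(spanBp / 15000)),
               medLog2R = ml, medMBAF = mb, genomeBp = genome)
}
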