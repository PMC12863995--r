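#' Create a run configuration
#'
#' All tunables of the pipeline with their defaults. Argument names are
#' the keys accepted by the configuration file (see [readRunConfig()]).
#'
#' @param footprint_fraction Clone-calling footprint as a fraction of the
#'   analyzed genome (default 0.01).
#' @param delta_f Fraction-cluster merge tolerance (default 0.08).
#' @param tau_log2r,tau_mbaf Aberrance thresholds on segment medians
#'   (defaults 0.15 and 0.58).
#' @param min_probes Minimum probes per emitted segment (default 50).
#' @param max_total_copy Copy-state grid cap (default 4).
#' @param mono_if_cc_le Mono-CC cutoff (default 0: Mono means CC = 0).
#' @param informative_baf_window BAF window for heterozygous-like probes
#'   (default `c(0.03, 0.97)`).
#' @param min_informative Minimum informative probes for a segment
#'   mirrored-BAF summary (default 10).
#' @param split_penalty Change-point acceptance penalty lambda (default 10).
#' @param merge_tol_log2r,merge_tol_mbaf Post-split re-merge tolerances
#'   (defaults 0.05, 0.02).
#' @param weight_log2r,weight_baf Fitting residual weights (defaults 1, 4).
#' @param rng_seed Optional integer seed recorded in reports.
#' @return A validated [RunConfig-class].
#' @examples
#' cfg <- ccConfig(footprint_fraction = 0.005) # sensitivity setting
#' @export
ccConfig <- function(footprint_fraction = 0.01, delta_f = 0.08,
                     tau_log2r = 0.15, tau_mbaf = 0.58, min_probes = 50L,
                     max_total_copy = 4L, mono_if_cc_le = 0L,
                     informative_baf_window = c(0.03, 0.97),
                     min_informative = 10L, split_penalty = 10,
                     merge_tol_log2r = 0.05, merge_tol_mbaf = 0.02,
                     weight_log2r = 1, weight_baf = 4, rng_seed = NA_integer_) {
    new("RunConfig",
        footprint_fraction = as.numeric(footprint_fraction),
        delta_f = as.numeric(delta_f), tau_log2r = as.numeric(tau_log2r),
        tau_mbaf = as.numeric(tau_mbaf), min_probes = as.integer(min_probes),
        max_total_copy = as.integer(max_total_copy),
        mono_if_cc_le = as.integer(mono_if_cc_le),
        informative_baf_window = as.numeric(informative_baf_window),
        min_informative = as.integer(min_informative),
        split_penalty = as.numeric(split_penalty),
        merge_tol_log2r = as.numeric(merge_tol_log2r),
        merge_tol_mbaf = as.numeric(merge_tol_mbaf),
        weight_log2r = as.numeric(weight_log2r),
        weight_baf = as.numeric(weight_baf),
        rng_seed = as.integer(rng_seed))
}

.configFields <- function() setdiff(slotNames("RunConfig"), character())

.configAsList <- function(cfg) {
    out <- lapply(.configFields(), function(s) slot(cfg, s))
    names(out) <- .configFields()
    out
}

#' Construct a ProbeSet
#'
#' @param chrom Autosome labels ("1".."22"; an optional "chr" prefix is
#'   stripped).
#' @param pos 1-based positions.
#' @param log2r,baf Per-probe signals.
#' @param sampleId Sample identifier.
#' @return A sorted, validated [ProbeSet-class].
#' @export
probeSet <- function(chrom, pos, log2r, baf, sampleId = "sample") {
    chrom <- .normChrom(chrom)
    if (anyNA(chrom)) stop("non-autosomal chromosome label")
    o <- order(.chromOrder(chrom), pos)
    gr <- GRanges(chrom[o], IRanges(pos[o], width = 1L))
    mcols(gr)$log2r <- as.numeric(log2r[o])
    mcols(gr)$baf <- as.numeric(baf[o])
    new("ProbeSet", ranges = gr, sampleId = as.character(sampleId))
}

#' Construct a SegmentSet
#'
#' @param chrom,start,end Segment coordinates (1-based inclusive).
#' @param numProbes Probe counts per segment.
#' @param medLog2R Median log2R per segment.
#' @param medMBAF Median mirrored BAF per segment (`NA` when the segment
#'   is BAF-uninformative).
#' @param genomeBp Analyzed autosomal span (footprint denominator).
#' @param sampleId Sample identifier.
#' @return A validated [SegmentSet-class], sorted by (chrom, start).
#' @export
segmentSet <- function(chrom, start, end, numProbes, medLog2R,
                       medMBAF = NA_real_, genomeBp, sampleId = "sample") {
    chrom <- .normChrom(chrom)
    if (anyNA(chrom)) stop("non-autosomal chromosome label")
    n <- length(chrom)
    medMBAF <- rep_len(as.numeric(medMBAF), n)
    o <- order(.chromOrder(chrom), start)
    gr <- GRanges(chrom[o], IRanges(start[o], end[o]))
    mcols(gr)$numProbes <- as.integer(rep_len(numProbes, n)[o])
    mcols(gr)$medLog2R <- as.numeric(rep_len(medLog2R, n)[o])
    mcols(gr)$medMBAF <- medMBAF[o]
    new("SegmentSet", ranges = gr, genomeBp = as.numeric(genomeBp),
        sampleId = as.character(sampleId))
}

#' Construct a clonal architecture
#'
#' @param purity Tumor purity in (0, 1].
#' @param clones data.frame with `clone_id`, `ccf`.
#' @param events data.frame with `chrom`, `start`, `end`, `n_total`,
#'   `n_minor`, `clone_id`.
#' @param nested Allow overlapping events of different clones (innermost
#'   wins when rendering); default `FALSE`.
#' @return A validated [ClonalArchitecture-class].
#' @examples
#' arch <- clonalArchitecture(
#'   purity = 0.6,
#'   clones = data.frame(clone_id = "c1", ccf = 1),
#'   events = data.frame(chrom = "4", start = 1e6, end = 31e6,
#'                       n_total = 1L, n_minor = 0L, clone_id = "c1"))
#' @export
clonalArchitecture <- function(purity, clones, events =
        data.frame(chrom = character(), start = numeric(), end = numeric(),
                   n_total = integer(), n_minor = integer(),
                   clone_id = character()), nested = FALSE) {
    events$chrom <- .normChrom(events$chrom)
    new("ClonalArchitecture", purity = as.numeric(purity),
        clones = as.data.frame(clones), events = as.data.frame(events),
        nested = isTRUE(nested))
}

#' Construct a noise model
#'
#' @param sigmaLog2R Gaussian SD of per-probe log2R noise (default 0.25;
#'   0 for the exact limit).
#' @param bafConcentration Beta precision of per-probe BAF (default 60;
#'   `Inf` for the exact limit).
#' @param hetFraction Germline heterozygosity rate (default 0.35).
#' @param nProbes Array size (default 220000).
#' @return A validated [NoiseModel-class].
#' @export
noiseModel <- function(sigmaLog2R = 0.25, bafConcentration = 60,
                       hetFraction = 0.35, nProbes = 220000L) {
    new("NoiseModel", sigmaLog2R = as.numeric(sigmaLog2R),
        bafConcentration = as.numeric(bafConcentration),
        hetFraction = as.numeric(hetFraction), nProbes = as.integer(nProbes))
}

#' Zero-noise model (exact expectations)
#'
#' Convenience wrapper: probes are rendered at their exact expected
#' log2R/BAF values. Used by recovery tests.
#' @param nProbes Array size (default 220000).
#' @return A [NoiseModel-class] with `sigmaLog2R = 0`,
#'   `bafConcentration = Inf`.
#' @export
exactNoiseModel <- function(nProbes = 220000L)
    noiseModel(sigmaLog2R = 0, bafConcentration = Inf, nProbes = nProbes)
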