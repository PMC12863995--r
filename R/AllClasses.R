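#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

#' Run configuration for the clonal-composition pipeline
#'
#' Holds every tunable of the segmentation, segment-fitting, fraction
#' clustering and clone-calling stages. Slot names double as the keys of
#' the plain-text configuration file read by [readRunConfig()].
#'
#' @slot footprint_fraction Minimum fraction of the analyzed genome a
#'   fraction cluster must span to be counted as a clone (default 0.01,
#'   i.e. the 1\% clone-calling footprint; 0.005 is the sensitivity
#'   setting).
#' @slot delta_f Maximum distance between a fitted cellular fraction and
#'   the running cluster centroid for the segment to join the cluster
#'   (default 0.08).
#' @slot tau_log2r Absolute segment-median log2R at or above which a
#'   segment is called copy-number aberrant (default 0.15).
#' @slot tau_mbaf Segment-median mirrored BAF at or above which a segment
#'   is called allelically aberrant (default 0.58).
#' @slot min_probes Minimum probes for a segment to be emitted (default 50).
#' @slot max_total_copy Largest total copy number in the fitting grid
#'   (default 4).
#' @slot mono_if_cc_le Classification is Mono-CC when CC is at or below
#'   this value (default 0).
#' @slot informative_baf_window BAF window retaining approximately
#'   germline-heterozygous probes (default `c(0.03, 0.97)`).
#' @slot min_informative Minimum informative probes for a segment to carry
#'   a mirrored-BAF summary (default 10).
#' @slot split_penalty BIC-style penalty multiplier lambda for accepting a
#'   change point (default 10; threshold is lambda * log(n) per
#'   chromosome, on channels z-scaled by their genome-wide MAD).
#' @slot merge_tol_log2r,merge_tol_mbaf Adjacent segments whose medians
#'   differ by less than both tolerances are re-merged (defaults 0.05 and
#'   0.02).
#' @slot weight_log2r,weight_baf Residual weights of the two channels in
#'   segment fitting (defaults 1 and 4; the BAF channel is less noisy
#'   after median summarization).
#' @slot rng_seed Optional integer seed recorded in reports.
#' @seealso [ccConfig()]
#' @exportClass RunConfig
setClass("RunConfig", representation(
    footprint_fraction = "numeric",
    delta_f = "numeric",
    tau_log2r = "numeric",
    tau_mbaf = "numeric",
    min_probes = "integer",
    max_total_copy = "integer",
    mono_if_cc_le = "integer",
    informative_baf_window = "numeric",
    min_informative = "integer",
    split_penalty = "numeric",
    merge_tol_log2r = "numeric",
    merge_tol_mbaf = "numeric",
    weight_log2r = "numeric",
    weight_baf = "numeric",
    rng_seed = "integer"
))

setValidity("RunConfig", function(object) {
    msg <- character()
    if (!(object@footprint_fraction > 0 && object@footprint_fraction < 1))
        msg <- c(msg, "footprint_fraction must lie in (0, 1)")
    if (!(object@delta_f > 0 && object@delta_f < 0.5))
        msg <- c(msg, "delta_f must lie in (0, 0.5)")
    if (object@max_total_copy < 3L)
        msg <- c(msg, "max_total_copy must be >= 3")
    if (object@tau_log2r <= 0) msg <- c(msg, "tau_log2r must be positive")
    if (!(object@tau_mbaf > 0.5 && object@tau_mbaf <= 1))
        msg <- c(msg, "tau_mbaf must lie in (0.5, 1]")
    w <- object@informative_baf_window
    if (length(w) != 2L || w[1] < 0 || w[2] > 1 || w[1] >= w[2])
        msg <- c(msg, "informative_baf_window must be an increasing pair in [0, 1]")
    if (object@min_probes < 1L) msg <- c(msg, "min_probes must be >= 1")
    if (object@mono_if_cc_le < 0L) msg <- c(msg, "mono_if_cc_le must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Probe-level allele-specific array data
#'
#' One record per autosomal polymorphic locus, carrying the log2 ratio of
#' total copy signal (log2R) and the B-allele frequency (BAF). Records are
#' stored as a width-1 [GenomicRanges::GRanges] sorted by chromosome
#' (numeric order 1..22) then position, with metadata columns `log2r` and
#' `baf`. Coordinates are 1-based.
#'
#' @slot ranges `GRanges` of probe positions with mcols `log2r`, `baf`.
#' @slot sampleId Sample identifier.
#' @seealso [readProbeTable()], [simulateSample()]
#' @exportClass ProbeSet
setClass("ProbeSet", representation(ranges = "GRanges", sampleId = "character"))

setValidity("ProbeSet", function(object) {
    gr <- object@ranges
    msg <- character()
    if (!all(as.character(seqnames(gr)) %in% AUTOSOMES))
        msg <- c(msg, "probes must lie on autosomes 1..22")
    b <- mcols(gr)$baf; l <- mcols(gr)$log2r
    if (is.null(b) || is.null(l))
        msg <- c(msg, "mcols must contain 'log2r' and 'baf'")
    else {
        if (any(!is.finite(l))) msg <- c(msg, "log2r must be finite")
        if (any(b < 0 | b > 1 | is.na(b))) msg <- c(msg, "baf must lie in [0, 1]")
        key <- paste(as.character(seqnames(gr)), start(gr))
        if (anyDuplicated(key)) msg <- c(msg, "duplicate (chrom, pos) records")
        o <- order(.chromOrder(as.character(seqnames(gr))), start(gr))
        if (!identical(o, seq_along(gr))) msg <- c(msg, "records not sorted by (chrom, pos)")
    }
    if (length(msg)) msg else TRUE
})

#' Genomic segments with summary BAF/log2R signals
#'
#' Non-overlapping (within chromosome) genomic intervals, each with the
#' number of member probes, the median log2R and — when at least
#' `min_informative` heterozygous-like probes contributed — the median
#' mirrored BAF (`NA` otherwise). 1-based inclusive coordinates.
#'
#' @slot ranges `GRanges` with mcols `numProbes`, `medLog2R`, `medMBAF`.
#' @slot genomeBp Total analyzed autosomal span in bp (footprint
#'   denominator); at least the summed segment lengths.
#' @slot sampleId Sample identifier.
#' @seealso [segmentGenome()], [readSeg()], [computeCC()]
#' @exportClass SegmentSet
setClass("SegmentSet", representation(ranges = "GRanges", genomeBp = "numeric",
                                      sampleId = "character"))

setValidity("SegmentSet", function(object) {
    gr <- object@ranges
    msg <- character()
    if (length(gr)) {
        if (!all(as.character(seqnames(gr)) %in% AUTOSOMES))
            msg <- c(msg, "segments must lie on autosomes 1..22")
        if (any(width(gr) < 1L)) msg <- c(msg, "segment length must be >= 1 bp")
        hits <- findOverlaps(gr, gr)
        if (any(queryHits(hits) != subjectHits(hits)))
            msg <- c(msg, "segments overlap within a chromosome")
        need <- c("numProbes", "medLog2R", "medMBAF")
        if (!all(need %in% names(mcols(gr))))
            msg <- c(msg, "mcols must contain numProbes, medLog2R, medMBAF")
        else {
            mb <- mcols(gr)$medMBAF
            if (any(!is.na(mb) & (mb < 0.5 | mb > 1)))
                msg <- c(msg, "medMBAF must lie in [0.5, 1] when present")
        }
        if (object@genomeBp < sum(as.numeric(width(gr))) - 0.5)
            msg <- c(msg, "genomeBp smaller than summed segment lengths")
    }
    if (object@genomeBp < 0) msg <- c(msg, "genomeBp must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Ground-truth clonal architecture for the simulator
#'
#' A tumor is modeled as an admixture of normal cells and one or more
#' tumor clones. `purity` is the fraction of cells that are tumor; each
#' clone has a cancer-cell fraction (CCF) `ccf`, so a copy-number event
#' carried by clone k is present in an overall cellular fraction
#' f = purity * ccf_k of all cells. Events are allele-specific:
#' `n_total` copies of which `n_minor` are the minor allele.
#'
#' @slot purity Tumor purity in (0, 1].
#' @slot clones data.frame with columns `clone_id`, `ccf` (each in (0, 1];
#'   a truncal/clonal event belongs to a clone with ccf = 1).
#' @slot events data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive bp), `n_total`, `n_minor`, `clone_id`.
#' @slot nested Allow events of different clones to overlap (a subclonal
#'   event on a clonal background); off by default because the fraction
#'   algebra of nested events is not modeled — the innermost (shortest)
#'   event wins for probe rendering.
#' @seealso [clonalArchitecture()], [simulateSample()]
#' @exportClass ClonalArchitecture
setClass("ClonalArchitecture", representation(
    purity = "numeric", clones = "data.frame", events = "data.frame",
    nested = "logical"))

setValidity("ClonalArchitecture", function(object) {
    msg <- character()
    if (!(object@purity > 0 && object@purity <= 1))
        msg <- c(msg, "purity must lie in (0, 1]")
    cl <- object@clones
    if (!all(c("clone_id", "ccf") %in% names(cl)))
        msg <- c(msg, "clones needs columns clone_id, ccf")
    else {
        if (any(cl$ccf <= 0 | cl$ccf > 1)) msg <- c(msg, "ccf must lie in (0, 1]")
        if (anyDuplicated(cl$clone_id)) msg <- c(msg, "duplicate clone_id")
    }
    ev <- object@events
    need <- c("chrom", "start", "end", "n_total", "n_minor", "clone_id")
    if (!all(need %in% names(ev)))
        msg <- c(msg, "events needs columns chrom, start, end, n_total, n_minor, clone_id")
    else if (nrow(ev)) {
        if (!all(as.character(ev$chrom) %in% AUTOSOMES))
            msg <- c(msg, "event chrom must be an autosome 1..22")
        if (any(ev$start < 1 | ev$end < ev$start))
            msg <- c(msg, "event intervals must satisfy 1 <= start <= end")
        if (any(ev$n_total < 0)) msg <- c(msg, "n_total must be >= 0")
        if (any(ev$n_minor < 0 | ev$n_minor > floor(ev$n_total / 2)))
            msg <- c(msg, "n_minor must satisfy 0 <= n_minor <= floor(n_total/2)")
        if (!all(ev$clone_id %in% cl$clone_id))
            msg <- c(msg, "event clone_id missing from clones")
        f <- object@purity * cl$ccf[match(ev$clone_id, cl$clone_id)]
        if (any(ev$n_total == 0 & f >= 1))
            msg <- c(msg, "total copy 0 at cellular fraction 1 is undefined")
        if (!isTRUE(object@nested)) {
            gr <- GRanges(as.character(ev$chrom), IRanges(ev$start, ev$end))
            hits <- findOverlaps(gr, gr)
            bad <- queryHits(hits) != subjectHits(hits)
            if (any(bad))
                msg <- c(msg, sprintf(
                    "events overlap (rows %s); set nested = TRUE to allow",
                    paste(unique(pmin(queryHits(hits)[bad], subjectHits(hits)[bad])),
                          collapse = ", ")))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Probe-level noise model
#'
#' FFPE-grade array noise: log2R gets i.i.d. Gaussian noise, BAF at
#' heterozygous loci is Beta-distributed around its expectation with
#' precision `bafConcentration` (bounded support — no values escape
#' \[0, 1\]), and homozygous loci are rendered as Beta draws centered at
#' 0.02 / 0.98 so that the downstream informative-probe filter has
#' realistic material to remove. `sigmaLog2R = 0` together with
#' `bafConcentration = Inf` is the exact (zero-noise) limit used by
#' recovery tests.
#'
#' @slot sigmaLog2R Per-probe SD of log2R (default 0.25).
#' @slot bafConcentration Beta precision kappa for BAF (default 60;
#'   `Inf` renders the exact expectation).
#' @slot hetFraction Probability a locus is germline-heterozygous
#'   (default 0.35).
#' @slot nProbes Number of autosomal probes (default 220000), placed
#'   uniformly over [autosomeLengths()].
#' @seealso [noiseModel()], [simulateSample()]
#' @exportClass NoiseModel
setClass("NoiseModel", representation(
    sigmaLog2R = "numeric", bafConcentration = "numeric",
    hetFraction = "numeric", nProbes = "integer"))

setValidity("NoiseModel", function(object) {
    msg <- character()
    if (object@sigmaLog2R < 0) msg <- c(msg, "sigmaLog2R must be >= 0")
    if (!(object@bafConcentration > 2)) msg <- c(msg, "bafConcentration must be > 2")
    if (!(object@hetFraction > 0 && object@hetFraction < 1))
        msg <- c(msg, "hetFraction must lie in (0, 1)")
    if (object@nProbes < 1L) msg <- c(msg, "nProbes must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Result of a clonal-composition analysis
#'
#' @slot cc The CC number: count of cellular-fraction clusters whose
#'   genomic footprint meets the configured threshold.
#' @slot classification `"Mono"` when `cc <= mono_if_cc_le` (default: CC
#'   = 0), `"Poly"` otherwise.
#' @slot clusters data.frame of every fraction cluster (passing or not):
#'   `centroid_f`, `footprint_bp`, `footprint_fraction`, `n_members`,
#'   `pass`; ordered by descending centroid.
#' @slot fits data.frame of per-segment fits: coordinates, summaries,
#'   `aberrant` flag, fitted `n_total`, `n_minor`, `f`, `residual`,
#'   `cluster` (index into `clusters`, NA for non-aberrant segments).
#' @slot genomeBp Footprint denominator used (analyzed autosomal span).
#' @slot sampleId Sample identifier.
#' @slot config The [RunConfig-class] used.
#' @seealso [computeCC()], [writeCCReport()]
#' @exportClass CCResult
setClass("CCResult", representation(
    cc = "integer", classification = "character", clusters = "data.frame",
    fits = "data.frame", genomeBp = "numeric", sampleId = "character",
    config = "RunConfig"))

setValidity("CCResult", function(object) {
    msg <- character()
    if (object@cc < 0L) msg <- c(msg, "cc must be >= 0")
    if (nrow(object@clusters) && object@cc != sum(object@clusters$pass))
        msg <- c(msg, "cc must equal the number of pass-flagged clusters")
    if (!object@classification %in% c("Mono", "Poly"))
        msg <- c(msg, "classification must be 'Mono' or 'Poly'")
    wantMono <- object@cc <= object@config@mono_if_cc_le
    if ((object@classification == "Mono") != wantMono)
        msg <- c(msg, "classification inconsistent with cc and config")
    if (length(msg)) msg else TRUE
})
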