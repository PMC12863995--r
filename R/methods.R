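#' Accessors
#'
#' Extract the components of the package's S4 objects without touching
#' slots directly.
#'
#' @param x A `ProbeSet`, `SegmentSet` or `CCResult`.
#' @return `probeRanges`/`segmentRanges`: a `GRanges`; `genomeBp`,
#'   `ccNumber`: a number; `sampleId`, `ccClass`: a string;
#'   `ccClusters`, `segmentFits`: a data.frame.
#' @name accessors
NULL

#' @rdname accessors
setMethod("sampleId", "ProbeSet", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "SegmentSet", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "CCResult", function(x) x@sampleId)
#' @rdname accessors
setMethod("probeRanges", "ProbeSet", function(x) x@ranges)
#' @rdname accessors
setMethod("segmentRanges", "SegmentSet", function(x) x@ranges)
#' @rdname accessors
setMethod("genomeBp", "SegmentSet", function(x) x@genomeBp)
#' @rdname accessors
setMethod("genomeBp", "CCResult", function(x) x@genomeBp)
#' @rdname accessors
setMethod("ccNumber", "CCResult", function(x) x@cc)
#' @rdname accessors
setMethod("ccClass", "CCResult", function(x) x@classification)
#' @rdname accessors
setMethod("ccClusters", "CCResult", function(x) x@clusters)
#' @rdname accessors
setMethod("segmentFits", "CCResult", function(x) x@fits)

#' @rdname accessors
setMethod("length", "ProbeSet", function(x) length(x@ranges))
#' @rdname accessors
setMethod("length", "SegmentSet", function(x) length(x@ranges))

setMethod("show", "ProbeSet", function(object) {
    cat("ProbeSet '", object@sampleId, "': ", length(object@ranges),
        " probes on ", length(unique(as.character(seqnames(object@ranges)))),
        " autosomes\n", sep = "")
})

setMethod("show", "SegmentSet", function(object) {
    cat("SegmentSet '", object@sampleId, "': ", length(object@ranges),
        " segments, analyzed span ", format(object@genomeBp, big.mark = ","),
        " bp\n", sep = "")
})

setMethod("show", "RunConfig", function(object) {
    cat("RunConfig:\n")
    for (s in slotNames(object))
        cat("  ", s, " = ", paste(format(slot(object, s)), collapse = ", "),
            "\n", sep = "")
})

setMethod("show", "ClonalArchitecture", function(object) {
    cat("ClonalArchitecture: purity ", object@purity, ", ",
        nrow(object@clones), " clone(s), ", nrow(object@events),
        " event(s)\n", sep = "")
})

setMethod("show", "NoiseModel", function(object) {
    cat("NoiseModel: sigmaLog2R ", object@sigmaLog2R,
        ", bafConcentration ", object@bafConcentration,
        ", hetFraction ", object@hetFraction,
        ", nProbes ", object@nProbes, "\n", sep = "")
})

setMethod("show", "CCResult", function(object) {
    cat("CCResult '", object@sampleId, "': CC = ", object@cc, " (",
        object@classification, "-CC)\n", sep = "")
    cl <- object@clusters
    if (nrow(cl)) {
        cat(sprintf("  %d fraction cluster(s), footprint threshold %.3g of %s bp:\n",
                    nrow(cl), object@config@footprint_fraction,
                    format(object@genomeBp, big.mark = ",")))
        for (i in seq_len(nrow(cl)))
            cat(sprintf("    f = %.2f  span %.2f%%  members %d  %s\n",
                        cl$centroid_f[i], 100 * cl$footprint_fraction[i],
                        cl$n_members[i], if (cl$pass[i]) "PASS" else "below footprint"))
    } else cat("  no aberrant segments\n")
})
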