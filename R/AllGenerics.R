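#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("probeRanges", function(x) standardGeneric("probeRanges"))

#' @rdname accessors
#' @export
setGeneric("segmentRanges", function(x) standardGeneric("segmentRanges"))

#' @rdname accessors
#' @export
setGeneric("genomeBp", function(x) standardGeneric("genomeBp"))

#' @rdname accessors
#' @export
setGeneric("ccNumber", function(x) standardGeneric("ccNumber"))

#' @rdname accessors
#' @export
setGeneric("ccClass", function(x) standardGeneric("ccClass"))

#' @rdname accessors
#' @export
setGeneric("ccClusters", function(x) standardGeneric("ccClusters"))

#' @rdname accessors
#' @export
setGeneric("segmentFits", function(x) standardGeneric("segmentFits"))

#' Compute the clonal-composition number
#'
#' @param x A [SegmentSet-class] (or a [ProbeSet-class], which is first
#'   segmented with [segmentGenome()]).
#' @param cfg A [RunConfig-class]; see [ccConfig()].
#' @return A [CCResult-class].
#' @seealso [fitSegments()], [clusterFractions()]
#' @export
setGeneric("computeCC", function(x, cfg = ccConfig()) standardGeneric("computeCC"))
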