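#' Call a segment copy-number aberrant
#'
#' A segment is aberrant when its median log2R deviates by at least
#' `tau_log2r` from 0, or its median mirrored BAF (when present) is at
#' least `tau_mbaf`. Non-aberrant segments are treated as the normal
#' diploid heterozygous state and never receive a fraction fit.
#'
#' @param medLog2R,medMBAF Segment medians (vectorized; `medMBAF` may be
#'   `NA` for BAF-uninformative segments).
#' @param cfg A [RunConfig-class].
#' @return Logical vector.
#' @export
isAberrant <- function(medLog2R, medMBAF = NA_real_, cfg = ccConfig()) {
    abs(medLog2R) >= cfg@tau_log2r |
        (!is.na(medMBAF) & medMBAF >= cfg@tau_mbaf)
}

# enumerate the aberrant copy-state grid: nT in 0..max, 0 <= nB <=
# floor(nT/2), excluding the normal (2, 1)
.stateGrid <- function(maxTotal) {
    states <- do.call(rbind, lapply(0:maxTotal, function(nT)
        data.frame(nT = nT, nB = 0:(nT %/% 2))))
    states[!(states$nT == 2 & states$nB == 1), , drop = FALSE]
}

#' Fit an allele-specific copy state and cellular fraction to a segment
#'
#' Exhaustive grid search over copy states (total copies 0..
#' `max_total_copy`, minor copies up to half, excluding the normal
#' (2, 1)) and cellular fractions f = 0.01, 0.02, ..., 1.00, minimizing
#' the weighted squared error
#' `weight_log2r * (medLog2R - expectedLog2R(f, nT))^2 +
#'  weight_baf * (medMBAF - mirrored expectedBAF(f, nT, nB))^2`.
#' When the segment carries no mirrored-BAF summary the BAF term is
#' omitted and states are distinguishable only through total copy
#' number. Ties are broken toward the smaller `|nT - 2|`, then the
#' larger `nB`, then the smaller f.
#'
#' @param medLog2R,medMBAF Segment medians (`medMBAF = NA` when absent).
#' @param cfg A [RunConfig-class].
#' @return A list with `n_total`, `n_minor`, `f`, `residual`.
#' @examples
#' fitSegment(expectedLog2R(0.6, 1),
#'            1 - expectedBAF(0.6, 1, 0)) # state (1, 0), f = 0.60
#' @export
fitSegment <- function(medLog2R, medMBAF = NA_real_, cfg = ccConfig()) {
    states <- .stateGrid(cfg@max_total_copy)
    fGrid <- seq(0.01, 1, by = 0.01)
    best <- NULL
    for (s in seq_len(nrow(states))) {
        nT <- states$nT[s]; nB <- states$nB[s]
        ok <- !(nT == 0 & fGrid >= 1)  # nT=0 at f=1 has no defined signal
        f <- fGrid[ok]
        el <- expectedLog2R(f, nT)
        res <- cfg@weight_log2r * (medLog2R - el)^2
        if (!is.na(medMBAF)) {
            eb <- expectedBAF(f, nT, nB)
            emb <- 0.5 + abs(eb - 0.5)
            res <- res + cfg@weight_baf * (medMBAF - emb)^2
        }
        i <- which.min(res)
        cand <- data.frame(nT = nT, nB = nB, f = f[i], residual = res[i])
        best <- rbind(best, cand)
    }
    # minimum residual with tie-breaks (numerical ties within 1e-12)
    best <- best[best$residual <= min(best$residual) + 1e-12, , drop = FALSE]
    best <- best[order(abs(best$nT - 2), -best$nB, best$f), , drop = FALSE]
    list(n_total = as.integer(best$nT[1]), n_minor = as.integer(best$nB[1]),
         f = best$f[1], residual = best$residual[1])
}

#' Fit every segment of a SegmentSet
#'
#' Applies [isAberrant()] and, for aberrant segments, [fitSegment()].
#'
#' @param x A [SegmentSet-class].
#' @param cfg A [RunConfig-class].
#' @return A data.frame with one row per segment: `chrom`, `start`,
#'   `end`, `length_bp`, `n_probes`, `med_log2r`, `med_mbaf`,
#'   `aberrant`, and (aberrant rows only) `n_total`, `n_minor`, `f`,
#'   `residual`.
#' @export
fitSegments <- function(x, cfg = ccConfig()) {
    stopifnot(is(x, "SegmentSet"))
    gr <- x@ranges
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr), end = end(gr),
                     length_bp = as.numeric(width(gr)),
                     n_probes = mcols(gr)$numProbes,
                     med_log2r = mcols(gr)$medLog2R,
                     med_mbaf = mcols(gr)$medMBAF,
                     stringsAsFactors = FALSE)
    df$aberrant <- isAberrant(df$med_log2r, df$med_mbaf, cfg)
    df$n_total <- NA_integer_; df$n_minor <- NA_integer_
    df$f <- NA_real_; df$residual <- NA_real_
    for (i in which(df$aberrant)) {
        fit <- fitSegment(df$med_log2r[i], df$med_mbaf[i], cfg)
        df$n_total[i] <- fit$n_total; df$n_minor[i] <- fit$n_minor
        df$f[i] <- fit$f; df$residual[i] <- fit$residual
    }
    df
}

#' Cluster segment cellular fractions
#'
#' One-dimensional agglomerative merge: fits are sorted by fraction
#' (ties broken by genomic order), and a new cluster starts whenever the
#' next fraction differs from the running length-weighted centroid by
#' more than `delta_f`. The result is deterministic and independent of
#' the input row order.
#'
#' @param fits data.frame of aberrant segment fits (columns `f`,
#'   `length_bp`, `chrom`, `start`; typically the aberrant rows of
#'   [fitSegments()]).
#' @param cfg A [RunConfig-class].
#' @return A list with `clusters` (data.frame `centroid_f`,
#'   `footprint_bp`, `n_members`, ordered by descending centroid) and
#'   `assignment` (cluster index per input row).
#' @export
clusterFractions <- function(fits, cfg = ccConfig()) {
    if (is.null(fits) || !nrow(fits)) {
        return(list(clusters = data.frame(centroid_f = numeric(),
                                          footprint_bp = numeric(),
                                          n_members = integer()),
                    assignment = integer()))
    }
    o <- order(fits$f, .chromOrder(fits$chrom), fits$start)
    f <- fits$f[o]; wbp <- as.numeric(fits$length_bp[o])
    cl <- integer(length(f))
    centroid <- f[1]; wsum <- wbp[1]; cur <- 1L
    cl[1] <- 1L
    for (i in seq_along(f)[-1]) {
        if (abs(f[i] - centroid) > cfg@delta_f) {
            cur <- cur + 1L
            centroid <- f[i]; wsum <- wbp[i]
        } else {
            centroid <- (centroid * wsum + f[i] * wbp[i]) / (wsum + wbp[i])
            wsum <- wsum + wbp[i]
        }
        cl[i] <- cur
    }
    agg <- data.frame(
        centroid_f = as.numeric(tapply(f * wbp, cl, sum) / tapply(wbp, cl, sum)),
        footprint_bp = as.numeric(tapply(wbp, cl, sum)),
        n_members = as.integer(table(cl)))
    ord <- order(-agg$centroid_f)
    agg <- agg[ord, , drop = FALSE]
    rownames(agg) <- NULL
    relabel <- match(seq_len(nrow(agg)), ord)
    assignment <- integer(nrow(fits))
    assignment[o] <- relabel[cl]
    list(clusters = agg, assignment = assignment)
}

#' @describeIn computeCC Compute CC from pre-computed segments: fit every
#'   aberrant segment, cluster the fractions, flag clusters whose
#'   genomic footprint reaches `footprint_fraction` of the analyzed
#'   genome, and count them. Classification is Mono when
#'   `cc <= mono_if_cc_le`.
#' @export
setMethod("computeCC", "SegmentSet", function(x, cfg = ccConfig()) {
    if (x@genomeBp <= 0) stop("genomeBp must be positive")
    fits <- fitSegments(x, cfg)
    ab <- fits[fits$aberrant, , drop = FALSE]
    clu <- clusterFractions(ab, cfg)
    clusters <- clu$clusters
    clusters$footprint_fraction <- clusters$footprint_bp / x@genomeBp
    clusters$pass <- clusters$footprint_fraction >= cfg@footprint_fraction
    clusters <- clusters[, c("centroid_f", "footprint_bp",
                             "footprint_fraction", "n_members", "pass")]
    fits$cluster <- NA_integer_
    fits$cluster[fits$aberrant] <- clu$assignment
    cc <- as.integer(sum(clusters$pass))
    new("CCResult", cc = cc,
        classification = if (cc <= cfg@mono_if_cc_le) "Mono" else "Poly",
        clusters = clusters, fits = fits, genomeBp = x@genomeBp,
        sampleId = x@sampleId, config = cfg)
})

#' @describeIn computeCC Segment the probes with [segmentGenome()], then
#'   compute CC.
#' @export
setMethod("computeCC", "ProbeSet", function(x, cfg = ccConfig()) {
    computeCC(segmentGenome(x, cfg), cfg)
})
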