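#' Mirrored B-allele frequency
#'
#' Folds BAF about 0.5 (`0.5 + |baf - 0.5|`), removing the unknown allele
#' phase; the result lies in \[0.5, 1\].
#'
#' @param baf Numeric in \[0, 1\] (vectorized).
#' @return Mirrored BAF.
#' @examples
#' mirroredBAF(c(0.2, 0.5, 0.8)) # 0.8 0.5 0.8
#' @export
mirroredBAF <- function(baf) {
    if (any(baf < 0 | baf > 1 | is.na(baf))) stop("baf must lie in [0, 1]")
    0.5 + abs(baf - 0.5)
}

#' Select BAF-informative probes
#'
#' Keeps probes whose BAF lies inside `informative_baf_window`
#' (default \[0.03, 0.97\], inclusive). Without a matched normal these
#' approximate germline heterozygotes; homozygous probes pile up near 0
#' and 1 and carry no allelic signal.
#'
#' @param x A [ProbeSet-class].
#' @param cfg A [RunConfig-class].
#' @return A [ProbeSet-class] restricted to informative probes.
#' @export
selectInformative <- function(x, cfg = ccConfig()) {
    stopifnot(is(x, "ProbeSet"))
    w <- cfg@informative_baf_window
    b <- mcols(x@ranges)$baf
    keep <- b >= w[1] & b <= w[2]
    new("ProbeSet", ranges = x@ranges[keep], sampleId = x@sampleId)
}

#' Segment the genome on joint log2R / mirrored-BAF signals
#'
#' Per chromosome, recursive binary change-point splitting on the
#' bivariate series (log2R, mirrored BAF of informative probes): a split
#' is accepted when it reduces the pooled within-segment sum of squared
#' deviations by more than `split_penalty * log(n)` (n = probes on the
#' chromosome), with both channels z-scaled by their genome-wide median
#' absolute deviation. Adjacent segments whose medians differ by less
#' than `merge_tol_log2r` log2R and `merge_tol_mbaf` mirrored BAF are
#' then re-merged, and only segments with at least `min_probes` probes
#' are emitted. Medians (not means) summarize each segment, for
#' robustness to FFPE outliers; the mirrored-BAF summary is reported
#' only when at least `min_informative` informative probes contributed.
#'
#' The footprint denominator `genomeBp` is the span of the analyzed
#' probes (per-chromosome first-to-last probe), not the full genome.
#'
#' @param x A [ProbeSet-class].
#' @param cfg A [RunConfig-class].
#' @return A [SegmentSet-class].
#' @seealso [computeCC()]
#' @export
segmentGenome <- function(x, cfg = ccConfig()) {
    stopifnot(is(x, "ProbeSet"))
    gr <- x@ranges
    chrom <- as.character(seqnames(gr))
    pos <- start(gr)
    l <- mcols(gr)$log2r
    b <- mcols(gr)$baf
    w <- cfg@informative_baf_window
    info <- b >= w[1] & b <= w[2]
    mb <- ifelse(info, mirroredBAF(b), NA_real_)

    byChrom <- split(seq_along(pos), factor(chrom, levels = AUTOSOMES))
    byChrom <- byChrom[lengths(byChrom) > 0]
    if (!length(byChrom) || max(lengths(byChrom)) < cfg@min_probes) {
        warning("too few probes to segment; returning empty SegmentSet")
        return(new("SegmentSet",
                   ranges = GRanges(), genomeBp = 0, sampleId = x@sampleId))
    }

    # genome-wide robust scales for the two channels
    sL <- .robustScale(l)
    sB <- .robustScale(mb[info])
    zl <- (l - stats::median(l)) / sL
    zb <- ifelse(info, (mb - stats::median(mb[info], na.rm = TRUE)) / sB, 0)

    out <- lapply(byChrom, function(idx) {
        bounds <- .binarySegment(zl[idx], zb[idx], info[idx],
                                 penalty = cfg@split_penalty * log(length(idx)))
        bounds <- .mergeAdjacent(bounds, l[idx], mb[idx], info[idx], cfg)
        keep <- (bounds[, 2] - bounds[, 1] + 1) >= cfg@min_probes
        bounds <- bounds[keep, , drop = FALSE]
        if (!nrow(bounds)) return(NULL)
        data.frame(
            chrom = chrom[idx[1]],
            start = pos[idx[bounds[, 1]]],
            end = pos[idx[bounds[, 2]]],
            numProbes = bounds[, 2] - bounds[, 1] + 1L,
            medLog2R = vapply(seq_len(nrow(bounds)), function(i)
                stats::median(l[idx[bounds[i, 1]:bounds[i, 2]]]), 0),
            medMBAF = vapply(seq_len(nrow(bounds)), function(i) {
                j <- idx[bounds[i, 1]:bounds[i, 2]]
                if (sum(info[j]) >= cfg@min_informative)
                    stats::median(mb[j], na.rm = TRUE) else NA_real_
            }, 0))
    })
    segs <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    span <- sum(vapply(byChrom, function(idx)
        as.numeric(pos[idx[length(idx)]] - pos[idx[1]] + 1), 0))
    if (is.null(segs) || !nrow(segs)) {
        warning("no segment reached min_probes; returning empty SegmentSet")
        return(new("SegmentSet", ranges = GRanges(), genomeBp = span,
                   sampleId = x@sampleId))
    }
    segmentSet(segs$chrom, segs$start, segs$end, segs$numProbes,
               segs$medLog2R, segs$medMBAF, genomeBp = span,
               sampleId = x@sampleId)
}

.robustScale <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(1)
    s <- stats::mad(v)
    if (s < 1e-6) s <- max(stats::sd(v), 1e-6)
    if (!is.finite(s) || s < 1e-6) s <- 1e-6
    s
}

# recursive binary segmentation on two channels given per-probe values
# (zb is 0 and masked where not informative); returns a matrix of
# [start, end] probe-index bounds in order
.binarySegment <- function(zl, zb, info, penalty) {
    n <- length(zl)
    # center per chromosome for numerical conditioning (deviation costs
    # are translation-invariant)
    zl <- zl - mean(zl)
    nb <- sum(info)
    if (nb > 0) zb[info] <- zb[info] - mean(zb[info])
    c1l <- cumsum(zl); c2l <- cumsum(zl^2)
    zbm <- ifelse(info, zb, 0)
    c1b <- cumsum(zbm); c2b <- cumsum(zbm^2); cnb <- cumsum(info)

    ssq <- function(i, j) {
        nl <- j - i + 1
        s1 <- c1l[j] - if (i > 1) c1l[i - 1] else 0
        s2 <- c2l[j] - if (i > 1) c2l[i - 1] else 0
        out <- s2 - s1^2 / nl
        nbq <- cnb[j] - if (i > 1) cnb[i - 1] else 0
        if (nbq > 0) {
            b1 <- c1b[j] - if (i > 1) c1b[i - 1] else 0
            b2 <- c2b[j] - if (i > 1) c2b[i - 1] else 0
            out <- out + b2 - b1^2 / nbq
        }
        max(out, 0)
    }
    bestSplit <- function(i, j) {
        k <- i:(j - 1)
        nlL <- k - i + 1; nlR <- j - k
        s1 <- c1l[i:j]; base1 <- if (i > 1) c1l[i - 1] else 0
        s2 <- c2l[i:j]; base2 <- if (i > 1) c2l[i - 1] else 0
        S1L <- (c1l[k] - base1); S2L <- (c2l[k] - base2)
        totL1 <- c1l[j] - base1; totL2 <- c2l[j] - base2
        costL <- S2L - S1L^2 / nlL
        costR <- (totL2 - S2L) - (totL1 - S1L)^2 / nlR
        baseB1 <- if (i > 1) c1b[i - 1] else 0
        baseB2 <- if (i > 1) c2b[i - 1] else 0
        baseBn <- if (i > 1) cnb[i - 1] else 0
        B1L <- c1b[k] - baseB1; B2L <- c2b[k] - baseB2
        BnL <- cnb[k] - baseBn
        totB1 <- c1b[j] - baseB1; totB2 <- c2b[j] - baseB2
        totBn <- cnb[j] - baseBn
        BnR <- totBn - BnL
        bL <- ifelse(BnL > 0, B2L - B1L^2 / pmax(BnL, 1), 0)
        bR <- ifelse(BnR > 0, (totB2 - B2L) - (totB1 - B1L)^2 / pmax(BnR, 1), 0)
        cost <- pmax(costL, 0) + pmax(costR, 0) + pmax(bL, 0) + pmax(bR, 0)
        kBest <- k[which.min(cost)]
        list(k = kBest, reduction = ssq(i, j) - min(cost))
    }
    segs <- list()
    recurse <- function(i, j) {
        if (j - i + 1 < 2) { segs[[length(segs) + 1]] <<- c(i, j); return() }
        sp <- bestSplit(i, j)
        if (sp$reduction > penalty) {
            recurse(i, sp$k)
            recurse(sp$k + 1, j)
        } else segs[[length(segs) + 1]] <<- c(i, j)
    }
    recurse(1, n)
    do.call(rbind, segs)
}

# merge adjacent probe-index segments whose raw medians are within the
# configured tolerances; iterate until stable
.mergeAdjacent <- function(bounds, l, mb, info, cfg) {
    medL <- function(b) stats::median(l[b[1]:b[2]])
    medB <- function(b) {
        j <- b[1]:b[2]
        if (sum(info[j]) >= cfg@min_informative)
            stats::median(mb[j], na.rm = TRUE) else NA_real_
    }
    repeat {
        if (nrow(bounds) < 2) return(bounds)
        mls <- apply(bounds, 1, medL)
        mbs <- apply(bounds, 1, medB)
        merged <- FALSE
        i <- 1
        out <- list()
        while (i <= nrow(bounds)) {
            if (i < nrow(bounds)) {
                dl <- abs(mls[i + 1] - mls[i])
                db <- abs(mbs[i + 1] - mbs[i])
                closeB <- is.na(db) || db < cfg@merge_tol_mbaf
                if (dl < cfg@merge_tol_log2r && closeB) {
                    out[[length(out) + 1]] <- c(bounds[i, 1], bounds[i + 1, 2])
                    i <- i + 2
                    merged <- TRUE
                    next
                }
            }
            out[[length(out) + 1]] <- bounds[i, ]
            i <- i + 1
        }
        bounds <- do.call(rbind, out)
        if (!merged) return(bounds)
    }
}
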