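#' Two-population copy-number mixture model
#'
#' A specimen is modeled as a mixture of normal diploid cells and cells
#' carrying a copy-number event in an overall cellular fraction f (the
#' product of tumor purity and the clone's cancer-cell fraction). The
#' average total copy number at an affected locus is
#' `2 (1 - f) + f nT`, giving
#' `log2R = log2( (2 (1 - f) + f nT) / 2 )`,
#' and for a germline-heterozygous locus the B-allele (minor-allele)
#' frequency is
#' `BAF = ( (1 - f) + f nB ) / ( 2 (1 - f) + f nT )`.
#'
#' @param f Overall cellular fraction in \[0, 1\] (vectorized).
#' @param nT Total copy number (integer >= 0).
#' @param nB Minor-allele copy number, `0 <= nB <= nT`.
#' @return `expectedLog2R`: the expected log2 ratio (0 when the mixture
#'   average copy is 2). `expectedBAF`: the expected BAF in \[0, 1\]
#'   (0.5 when f = 0 or the state is the normal (2, 1)).
#' @examples
#' expectedLog2R(0.5, 3)        # log2(2.5/2) = 0.32193
#' expectedBAF(0.5, 3, 2)       # 1.5/2.5 = 0.6
#' expectedBAF(0.6, 2, 0)       # cnLOH: 0.2, with expectedLog2R(0.6, 2) = 0
#' @name mixtureModel
NULL

#' @rdname mixtureModel
#' @export
expectedLog2R <- function(f, nT) {
    stopifnot(is.numeric(f), is.numeric(nT))
    if (any(f < 0 | f > 1 | is.na(f))) stop("f must lie in [0, 1]")
    if (any(nT < 0)) stop("nT must be >= 0")
    avg <- 2 * (1 - f) + f * nT
    if (any(avg <= 0)) stop("mixture average copy number is zero (nT = 0 at f = 1)")
    log2(avg / 2)
}

#' @rdname mixtureModel
#' @export
expectedBAF <- function(f, nT, nB) {
    stopifnot(is.numeric(f), is.numeric(nT), is.numeric(nB))
    if (any(f < 0 | f > 1 | is.na(f))) stop("f must lie in [0, 1]")
    if (any(nB < 0 | nB > nT)) stop("nB must satisfy 0 <= nB <= nT")
    den <- 2 * (1 - f) + f * nT
    if (any(den <= 0)) stop("undefined BAF: homozygous deletion in all cells")
    ((1 - f) + f * nB) / den
}

#' Invert the mixture model for the cellular fraction
#'
#' `fractionFromLog2R` solves the log2R equation for f given the total
#' copy number: `f = (2 * 2^log2r - 2) / (nT - 2)` (undefined at nT = 2,
#' where log2R carries no fraction information and the BAF channel must
#' be used). `fractionFromMBAF` solves the major-allele (mirrored BAF)
#' equation: with `b` the mirrored BAF,
#' `f = (2 b - 1) / ( (nT - nB - 1) - b (nT - 2) )`,
#' valid when the denominator is positive.
#'
#' Raw solutions are clipped to the fitting range \[0.01, 1\]; values
#' outside it are flagged.
#'
#' @param l2r Segment median log2R.
#' @param mbaf Segment median mirrored BAF in \[0.5, 1\].
#' @param nT,nB Candidate copy state.
#' @return A list with `f` (clipped), `raw` (unclipped solution) and
#'   `flagged` (`TRUE` where raw fell outside \[0.01, 1\]).
#' @examples
#' fractionFromLog2R(0.32193, 3)$f    # 0.5
#' fractionFromMBAF(0.8, 2, 0)$f      # cnLOH at f = 0.6
#' @name fractionInversion
NULL

.clipFraction <- function(raw) {
    flagged <- raw < 0.01 | raw > 1
    list(f = pmin(pmax(raw, 0.01), 1), raw = raw, flagged = flagged)
}

#' @rdname fractionInversion
#' @export
fractionFromLog2R <- function(l2r, nT) {
    if (any(nT == 2)) stop("nT = 2 leaves log2R uninformative; use the BAF channel")
    .clipFraction((2 * 2^l2r - 2) / (nT - 2))
}

#' @rdname fractionInversion
#' @export
fractionFromMBAF <- function(mbaf, nT, nB) {
    if (any(mbaf < 0.5 | mbaf > 1)) stop("mbaf must lie in [0.5, 1]")
    if (any(nT == 2 & nB == 1)) stop("(2, 1) is the normal state")
    den <- (nT - nB - 1) - mbaf * (nT - 2)
    if (any(den <= 0)) stop("state incompatible with mirrored BAF (non-positive denominator)")
    .clipFraction((2 * mbaf - 1) / den)
}
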