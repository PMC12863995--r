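#' Reference autosome lengths
#'
#' Lengths in base pairs of the 22 human autosomes (GRCh37 assembly),
#' used by the simulator to place probes and by truth-record bookkeeping.
#' Sex chromosomes are excluded throughout the package: BAF expectations
#' on X/Y depend on sex and are not modeled.
#'
#' @return Named numeric vector, names `"1"`..`"22"`, values in bp.
#' @examples
#' sum(autosomeLengths()) # ~2.88 Gb analyzed genome
#' @export
autosomeLengths <- function() {
    c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
      `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
      `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
      `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
      `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
      `21` = 48129895, `22` = 51304566)
}

AUTOSOMES <- as.character(1:22)

# strip an optional "chr" prefix and return NA for non-autosomes
.normChrom <- function(x) {
    x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
    x[!x %in% AUTOSOMES] <- NA_character_
    x
}

# chromosome sort key (numeric order 1..22)
.chromOrder <- function(chrom) match(as.character(chrom), AUTOSOMES)

.msg <- function(...) message("[cloneComp] ", ...)
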