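#' Published summary counts of the motivating DLBCL cohort
#'
#' Printed characteristics of a published cohort of 74 newly diagnosed
#' advanced-stage DLBCL patients whose tumors were classified Mono-CC
#' (CC = 0, n = 15) versus Poly-CC (CC >= 1, n = 59) by the
#' clonal-composition method this package implements. The patient-level
#' data are not public; these aggregate counts are the inputs for
#' reproducing the cohort's contingency statistics and CC-distribution
#' summaries.
#'
#' Contingency tables are oriented rows = Mono/Poly, columns = category
#' levels.
#'
#' @return A list:
#'   \describe{
#'     \item{n_mono, n_poly}{Group sizes (15, 59).}
#'     \item{cc_counts}{CC value -> patient count, whole cohort
#'       (0:15, 1:46, 2:11, 3:1, 4:1).}
#'     \item{cc_counts_poly}{Poly-CC group only.}
#'     \item{cc_counts_gcb_poly, cc_counts_abc_poly}{Poly-CC within the
#'       GCB and ABC cell-of-origin subtypes.}
#'     \item{tables}{2x2 (or 2x3) Mono-vs-Poly contingency tables:
#'       `ebv` (EBV-positive yes/no), `ecog` (performance status 0-1 vs
#'       2-4), `extranodal` (0-1 vs >= 2 sites), `stage` (III vs IV),
#'       `therapy` (R-CHOP / R-THPCOP / R-CVP).}
#'   }
#' @examples
#' fisherExact(dlbclCohortCounts()$tables$ebv) # 0.499
#' @export
dlbclCohortCounts <- function() {
    tbl <- function(mono, poly, levels) {
        m <- rbind(Mono = mono, Poly = poly)
        colnames(m) <- levels
        m
    }
    list(
        n_mono = 15L, n_poly = 59L,
        cc_counts = c(`0` = 15L, `1` = 46L, `2` = 11L, `3` = 1L, `4` = 1L),
        cc_counts_poly = c(`1` = 46L, `2` = 11L, `3` = 1L, `4` = 1L),
        cc_counts_gcb_poly = c(`1` = 20L, `2` = 4L),
        cc_counts_abc_poly = c(`1` = 21L, `2` = 7L, `4` = 1L),
        tables = list(
            ebv = tbl(c(1L, 14L), c(2L, 57L), c("Yes", "No")),
            ecog = tbl(c(14L, 1L), c(49L, 10L), c("0-1", "2-4")),
            extranodal = tbl(c(9L, 6L), c(31L, 28L), c("0-1", ">=2")),
            stage = tbl(c(4L, 11L), c(16L, 43L), c("III", "IV")),
            therapy = tbl(c(11L, 3L, 1L), c(41L, 18L, 0L),
                          c("R-CHOP", "R-THPCOP", "R-CVP"))))
}
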