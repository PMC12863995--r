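#' Read a probe-level BAF/log2R table
#'
#' Reads the tab-separated text export of an allele-specific SNP array
#' (one row per polymorphic locus). Coordinates are 1-based. Rows on sex
#' chromosomes, rows with missing signals, and rows with BAF outside
#' \[0, 1\] or non-finite log2R are dropped; every drop is counted and
#' reported via `message()`, never silent. Duplicate (chrom, pos) rows
#' keep the first occurrence.
#'
#' @param path Path to the TSV file (header required).
#' @param dialect Export dialect; only `"oncoscan_tsv"` is implemented.
#' @param colmap Named character vector mapping the internal fields
#'   `chrom`, `pos`, `log2r`, `baf` to header names.
#' @param sampleId Sample identifier (default: file base name).
#' @return A [ProbeSet-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' ps <- simulateSample(clonalArchitecture(0.6,
#'         data.frame(clone_id = "c", ccf = 1)),
#'         noiseModel(nProbes = 500L), seed = 1)$probes
#' writeProbeTable(ps, f)
#' ps2 <- readProbeTable(f)
#' @export
readProbeTable <- function(path, dialect = "oncoscan_tsv",
                           colmap = c(chrom = "Chromosome", pos = "Position",
                                      log2r = "Log2Ratio", baf = "BAF"),
                           sampleId = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("cannot read probe table: ", path)
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- colmap[c("chrom", "pos", "log2r", "baf")]
    missing <- need[!need %in% names(df)]
    if (length(missing))
        stop("probe table lacks column(s): ", paste(missing, collapse = ", "))
    chrom <- .normChrom(df[[need[["chrom"]]]])
    pos <- as.numeric(df[[need[["pos"]]]])
    l2r <- as.numeric(df[[need[["log2r"]]]])
    baf <- as.numeric(df[[need[["baf"]]]])

    nonAuto <- is.na(chrom)
    if (any(nonAuto)) .msg(sum(nonAuto), " non-autosomal row(s) dropped")
    bad <- !nonAuto & (is.na(baf) | is.na(l2r) | !is.finite(l2r) |
                           baf < 0 | baf > 1)
    if (any(bad)) .msg(sum(bad), " row(s) with missing or invalid BAF/log2R dropped")
    keep <- !nonAuto & !bad
    chrom <- chrom[keep]; pos <- pos[keep]; l2r <- l2r[keep]; baf <- baf[keep]
    dup <- duplicated(paste(chrom, pos))
    if (any(dup)) {
        .msg(sum(dup), " duplicate (chrom, pos) row(s) dropped")
        chrom <- chrom[!dup]; pos <- pos[!dup]
        l2r <- l2r[!dup]; baf <- baf[!dup]
    }
    if (!length(chrom)) stop("no usable probe rows in ", path)
    if (is.null(sampleId))
        sampleId <- sub("\\.[^.]*$", "", basename(path))
    probeSet(chrom, pos, l2r, baf, sampleId = sampleId)
}

#' Write a probe-level table
#'
#' Writes the TSV dialect read by [readProbeTable()] (columns
#' `Chromosome`, `Position`, `Log2Ratio`, `BAF`).
#'
#' @param x A [ProbeSet-class].
#' @param path Output path.
#' @return `invisible(path)`.
#' @export
writeProbeTable <- function(x, path) {
    stopifnot(is(x, "ProbeSet"))
    gr <- x@ranges
    df <- data.frame(Chromosome = as.character(seqnames(gr)),
                     Position = start(gr),
                     Log2Ratio = mcols(gr)$log2r,
                     BAF = mcols(gr)$baf)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write copy-number segments (SEG format)
#'
#' Standard tab-separated SEG: `Sample`, `Chromosome`, `Start`, `End`,
#' `Num_Probes`, `Segment_Mean`, with 1-based inclusive coordinates and
#' the segment mean interpreted as the median log2R. An optional extra
#' column `Segment_mBAF` carries the median mirrored BAF; segments
#' lacking it are flagged BAF-uninformative (`medMBAF = NA`).
#' Overlapping segments on a chromosome are a validation error.
#'
#' @param path SEG file path.
#' @param genomeBp Footprint denominator; default: the summed segment
#'   lengths.
#' @return `readSeg`: a [SegmentSet-class].
#' @export
readSeg <- function(path, genomeBp = NULL) {
    if (!file.exists(path)) stop("cannot read SEG file: ", path)
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("Sample", "Chromosome", "Start", "End", "Num_Probes", "Segment_Mean")
    missing <- need[!need %in% names(df)]
    if (length(missing))
        stop("SEG file lacks column(s): ", paste(missing, collapse = ", "))
    chrom <- .normChrom(df$Chromosome)
    if (anyNA(chrom)) {
        .msg(sum(is.na(chrom)), " non-autosomal segment(s) dropped")
        df <- df[!is.na(chrom), , drop = FALSE]
        chrom <- chrom[!is.na(chrom)]
    }
    if (!nrow(df)) stop("no autosomal segments in ", path)
    mbaf <- if ("Segment_mBAF" %in% names(df)) as.numeric(df$Segment_mBAF)
            else rep(NA_real_, nrow(df))
    o <- order(.chromOrder(chrom), df$Start)
    gr <- GRanges(chrom[o], IRanges(as.numeric(df$Start)[o], as.numeric(df$End)[o]))
    ov <- findOverlaps(gr, gr)
    bad <- queryHits(ov) != subjectHits(ov)
    if (any(bad))
        stop("overlapping segments in ", path, ": rows ",
             paste(sort(unique(c(queryHits(ov)[bad], subjectHits(ov)[bad]))),
                   collapse = ", "), " (after sorting)")
    if (is.null(genomeBp)) genomeBp <- sum(as.numeric(width(gr)))
    segmentSet(chrom[o], as.numeric(df$Start)[o], as.numeric(df$End)[o],
               numProbes = as.integer(df$Num_Probes)[o],
               medLog2R = as.numeric(df$Segment_Mean)[o],
               medMBAF = mbaf[o], genomeBp = genomeBp,
               sampleId = as.character(df$Sample[o][1]))
}

#' @rdname readSeg
#' @param x A [SegmentSet-class].
#' @return `writeSeg`: `invisible(path)`.
#' @export
writeSeg <- function(x, path) {
    stopifnot(is(x, "SegmentSet"))
    gr <- x@ranges
    df <- data.frame(Sample = x@sampleId,
                     Chromosome = as.character(seqnames(gr)),
                     Start = start(gr), End = end(gr),
                     Num_Probes = mcols(gr)$numProbes,
                     Segment_Mean = mcols(gr)$medLog2R,
                     Segment_mBAF = mcols(gr)$medMBAF)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a clinical cohort table
#'
#' CSV with one row per patient. Required columns: `patient_id`,
#' `efs_days`, `efs_event`, `os_days`, `os_event`; optional `cc`,
#' `cc_class`, `coo` and arbitrary covariates. Negative follow-up times
#' or event flags outside \{0, 1\} are rejected with an error. When `cc`
#' is present but `cc_class` is not, the class is derived under the
#' configured Mono rule.
#'
#' @param path CSV path.
#' @param cfg [RunConfig-class] supplying `mono_if_cc_le` for class
#'   derivation.
#' @return A data.frame.
#' @export
readClinicalCsv <- function(path, cfg = ccConfig()) {
    if (!file.exists(path)) stop("cannot read clinical table: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
    need <- c("patient_id", "efs_days", "efs_event", "os_days", "os_event")
    missing <- need[!need %in% names(df)]
    if (length(missing))
        stop("clinical table lacks required column(s): ",
             paste(missing, collapse = ", "))
    for (col in c("efs_days", "os_days")) {
        v <- as.numeric(df[[col]])
        if (any(is.na(v)) || any(v < 0))
            stop("negative or missing ", col, " in row(s) ",
                 paste(which(is.na(v) | v < 0), collapse = ", "))
        df[[col]] <- v
    }
    for (col in c("efs_event", "os_event")) {
        v <- as.integer(df[[col]])
        if (any(is.na(v)) || any(!v %in% 0:1))
            stop(col, " must be 0/1; offending row(s): ",
                 paste(which(is.na(v) | !v %in% 0:1), collapse = ", "))
        df[[col]] <- v
    }
    if ("cc" %in% names(df)) {
        df$cc <- as.integer(df$cc)
        if (any(df$cc < 0, na.rm = TRUE)) stop("cc must be >= 0")
        if (!"cc_class" %in% names(df))
            df$cc_class <- ifelse(df$cc <= cfg@mono_if_cc_le, "Mono", "Poly")
    }
    if ("cc_class" %in% names(df) && "cc" %in% names(df)) {
        ok <- is.na(df$cc) | is.na(df$cc_class) |
            (df$cc_class == ifelse(df$cc <= cfg@mono_if_cc_le, "Mono", "Poly"))
        if (!all(ok))
            stop("cc_class inconsistent with cc in row(s) ",
                 paste(which(!ok), collapse = ", "))
    }
    df
}

#' @rdname readClinicalCsv
#' @param x Cohort data.frame.
#' @export
writeClinicalCsv <- function(x, path) {
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "NA")
    invisible(path)
}

#' Write / read a clonal-composition JSON report
#'
#' The report carries the CC number, the Mono/Poly classification, every
#' fraction cluster (centroid, genomic footprint in bp and as a fraction,
#' pass flag, member segments with their fitted states), a full echo of
#' the run configuration and the package version. Keys are written in a
#' fixed order, and a report read back with [readCCReport()] and
#' re-serialized is byte-identical.
#'
#' @param x A [CCResult-class] (or a list previously returned by
#'   `readCCReport`).
#' @param path Output path.
#' @return `writeCCReport`: `invisible(path)`; `readCCReport`: the report
#'   as a nested list.
#' @export
writeCCReport <- function(x, path) {
    rep <- if (is(x, "CCResult")) .reportList(x) else x
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    invisible(path)
}

#' @rdname writeCCReport
#' @export
readCCReport <- function(path) {
    if (!file.exists(path)) stop("cannot read report: ", path)
    jsonlite::read_json(path, simplifyVector = FALSE)
}

.reportList <- function(res) {
    stopifnot(is(res, "CCResult"))
    cl <- res@clusters
    fits <- res@fits
    clusters <- lapply(seq_len(nrow(cl)), function(i) {
        members <- fits[!is.na(fits$cluster) & fits$cluster == i, , drop = FALSE]
        list(centroid_f = cl$centroid_f[i],
             footprint_bp = cl$footprint_bp[i],
             footprint_fraction = cl$footprint_fraction[i],
             pass = cl$pass[i],
             members = lapply(seq_len(nrow(members)), function(j)
                 list(chrom = members$chrom[j], start = members$start[j],
                      end = members$end[j], length_bp = members$length_bp[j],
                      n_total = members$n_total[j], n_minor = members$n_minor[j],
                      f = members$f[j])))
    })
    cfg <- .configAsList(res@config)
    # length-1 NA -> null; longer vectors as lists so that a report read
    # back and re-serialized is byte-identical
    cfg <- lapply(cfg, function(v) {
        if (length(v) == 1 && is.na(v)) NULL
        else if (length(v) > 1) as.list(v)
        else v
    })
    list(sample_id = res@sampleId, cc = res@cc,
         classification = res@classification,
         genome_bp = res@genomeBp, clusters = clusters, config = cfg,
         tool_version = as.character(utils::packageVersion("cloneComp")))
}

#' Read a run-configuration file
#'
#' YAML (or plain `key: value`) file; every [ccConfig()] field can be
#' overridden, unknown keys are an error.
#'
#' @param path Config file path.
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("cannot read config: ", path)
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(formals(ccConfig)))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    do.call(ccConfig, lapply(vals, unlist))
}
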