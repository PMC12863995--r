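#' Render a clonal architecture into noisy probe data
#'
#' Places `nProbes` loci uniformly over the 22 autosomes (proportionally
#' to [autosomeLengths()]), assigns every locus the copy state of the
#' event covering it (loci outside any event carry the normal state
#' (2, 1)), and renders signals under the mixture model: log2R is
#' Gaussian around [expectedLog2R()], BAF at germline-heterozygous loci
#' is Beta around [expectedBAF()] (with random allele phase, so raw BAF
#' splits symmetrically about 0.5), and homozygous loci are Beta around
#' 0.02 or 0.98. With `sigmaLog2R = 0` and `bafConcentration = Inf` the
#' exact expectations are rendered.
#'
#' The returned truth record counts the expected CC at the given
#' footprint: the number of distinct overall cellular fractions (rounded
#' to 0.01) among aberrant events whose aggregate span reaches
#' `footprint` times the autosomal genome.
#'
#' Output is fully determined by `seed` (same seed, byte-identical data).
#'
#' @param arch A [ClonalArchitecture-class].
#' @param noise A [NoiseModel-class].
#' @param seed Integer RNG seed.
#' @param footprint Clone-calling footprint used for the truth CC
#'   (default 0.01).
#' @param sampleId Sample identifier.
#' @return A list with `probes` (a [ProbeSet-class]) and `truth` (a list
#'   with `expected_cc`, `fractions` — aggregate span in bp per distinct
#'   fraction —, `footprint`, and the architecture).
#' @examples
#' arch <- clonalArchitecture(0.6, data.frame(clone_id = "c1", ccf = 1),
#'   data.frame(chrom = "4", start = 1e6, end = 31e6,
#'              n_total = 1L, n_minor = 0L, clone_id = "c1"))
#' sim <- simulateSample(arch, noiseModel(nProbes = 2000L), seed = 7)
#' sim$truth$expected_cc
#' @export
simulateSample <- function(arch, noise = noiseModel(), seed = 1L,
                           footprint = 0.01, sampleId = "sim") {
    stopifnot(is(arch, "ClonalArchitecture"), is(noise, "NoiseModel"))
    validObject(arch); validObject(noise)
    set.seed(as.integer(seed))
    lens <- autosomeLengths()
    nTot <- noise@nProbes
    alloc <- .allocateProbes(nTot, lens)

    chrom <- rep(names(lens), alloc)
    pos <- unlist(lapply(seq_along(lens), function(i)
        sort(sample.int(lens[i], alloc[i]))), use.names = FALSE)

    # per-probe copy state; events applied longest-first so that in
    # nested mode the innermost (shortest) event wins
    nT <- rep(2L, length(pos)); nB <- rep(1L, length(pos))
    f <- rep(0, length(pos))
    ev <- arch@events
    if (nrow(ev)) {
        fEv <- arch@purity * arch@clones$ccf[match(ev$clone_id, arch@clones$clone_id)]
        for (i in order(-(ev$end - ev$start))) {
            idx <- which(chrom == as.character(ev$chrom[i]) &
                             pos >= ev$start[i] & pos <= ev$end[i])
            nT[idx] <- as.integer(ev$n_total[i])
            nB[idx] <- as.integer(ev$n_minor[i])
            f[idx] <- fEv[i]
        }
    }

    het <- stats::runif(length(pos)) < noise@hetFraction
    eb <- expectedBAF(f, nT, nB)
    flip <- stats::runif(length(pos)) < 0.5
    muHet <- ifelse(flip, 1 - eb, eb)
    muHom <- ifelse(stats::runif(length(pos)) < 0.5, 0.02, 0.98)
    mu <- ifelse(het, muHet, muHom)
    kappa <- noise@bafConcentration
    baf <- if (is.finite(kappa))
        stats::rbeta(length(mu), mu * kappa, (1 - mu) * kappa) else mu
    baf[is.na(baf)] <- mu[is.na(baf)]  # rbeta returns NaN when a shape is 0

    muL <- expectedLog2R(f, nT)
    l2r <- if (noise@sigmaLog2R > 0)
        stats::rnorm(length(muL), muL, noise@sigmaLog2R) else muL

    probes <- probeSet(chrom, pos, l2r, baf, sampleId = sampleId)
    list(probes = probes,
         truth = .truthRecord(arch, footprint))
}

.allocateProbes <- function(nTot, lens) {
    share <- nTot * lens / sum(lens)
    alloc <- floor(share)
    rem <- nTot - sum(alloc)
    if (rem > 0) {
        extra <- order(share - alloc, decreasing = TRUE)[seq_len(rem)]
        alloc[extra] <- alloc[extra] + 1
    }
    as.integer(alloc)
}

.truthRecord <- function(arch, footprint) {
    ev <- arch@events
    genome <- sum(autosomeLengths())
    if (!nrow(ev)) {
        return(list(expected_cc = 0L, fractions = numeric(),
                    footprint = footprint, architecture = arch))
    }
    fEv <- arch@purity * arch@clones$ccf[match(ev$clone_id, arch@clones$clone_id)]
    aberrant <- !(ev$n_total == 2 & ev$n_minor == 1)
    fKey <- round(fEv[aberrant], 2)
    span <- tapply(ev$end[aberrant] - ev$start[aberrant] + 1, fKey, sum)
    span <- span[order(-as.numeric(names(span)))]
    list(expected_cc = as.integer(sum(span >= footprint * genome)),
         fractions = span, footprint = footprint, architecture = arch)
}

#' Deterministic architecture with a given truth CC
#'
#' Convenience generator used for cohort rendering and recovery grids:
#' `cc` clones at well-separated overall fractions (0.8, 0.55, 0.35 at
#' purity 1 scaling), each carrying one hemizygous deletion and one
#' copy-neutral LOH event of `eventMb` megabases on its own pair of
#' chromosomes (so per-clone footprints are about `2 * eventMb` Mb,
#' ~2.4\% of the genome at the default).
#'
#' @param cc Number of clones (0..3).
#' @param purity Tumor purity (default 0.8).
#' @param eventMb Span of each event in Mb (default 35).
#' @return A [ClonalArchitecture-class].
#' @export
architectureForCC <- function(cc, purity = 0.8, eventMb = 35) {
    stopifnot(cc %in% 0:3)
    fTarget <- c(0.8, 0.55, 0.35)[seq_len(cc)]
    clones <- data.frame(clone_id = paste0("c", seq_len(max(cc, 1))),
                         ccf = if (cc) fTarget / purity else 1)
    events <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), n_total = integer(),
                         n_minor = integer(), clone_id = character())
    if (cc) {
        span <- eventMb * 1e6
        rows <- lapply(seq_len(cc), function(k) {
            data.frame(chrom = as.character(c(2 * k - 1, 2 * k)),
                       start = 1e7, end = 1e7 + span - 1,
                       n_total = c(1L, 2L), n_minor = c(0L, 0L),
                       clone_id = clones$clone_id[k])
        })
        events <- do.call(rbind, rows)
    }
    clonalArchitecture(purity, clones, events)
}

#' Simulate a clinical cohort with group-specific hazards
#'
#' Generates a per-patient clinical table in the shape the cohort
#' statistics consume: a Mono/Poly CC classification (CC values drawn
#' from the empirical distribution of the motivating DLBCL cohort), a
#' cell-of-origin label, covariates, and exponential event-free and
#' overall survival times whose hazard is multiplied by `hazardRatio`
#' (EFS) and `osHazardRatio` (OS) in the Poly group. Censoring is
#' independent uniform on `censoring = c(lo, hi)` days, or absent when
#' `censoring = NULL`.
#'
#' @param nPatients Cohort size.
#' @param polyProb Probability of Poly-CC (default 59/74, the prevalence
#'   observed in the motivating cohort).
#' @param hazardRatio EFS hazard ratio Poly vs Mono (default 2.68).
#' @param osHazardRatio OS hazard ratio (default 1.27).
#' @param baseHazard Mono-group EFS hazard per day (default calibrated to
#'   a 69.1\% 5-year EFS).
#' @param baseOsHazard Mono-group OS hazard per day (default calibrated
#'   to a 66.2\% 5-year OS).
#' @param censoring Length-2 censoring window in days, or `NULL` for no
#'   censoring.
#' @param seed Integer RNG seed.
#' @param dir Optional output directory: writes `clinical.csv`,
#'   `truth.json` and, when `renderProbes = TRUE`, one probe TSV per
#'   patient via [simulateSample()] on [architectureForCC()].
#' @param renderProbes Also render per-patient probe files (slow; only
#'   sensible for small cohorts).
#' @param noise [NoiseModel-class] for probe rendering.
#' @return A list with `clinical` (data.frame) and `truth` (per-patient
#'   cc and group).
#' @examples
#' coh <- simulateCohort(200, seed = 1)
#' table(coh$clinical$cc_class)
#' @export
simulateCohort <- function(nPatients, polyProb = 59 / 74,
                           hazardRatio = 2.68, osHazardRatio = 1.27,
                           baseHazard = log(1 / 0.691) / 1825,
                           baseOsHazard = log(1 / 0.662) / 1825,
                           censoring = c(17, 2989), seed = 1L,
                           dir = NULL, renderProbes = FALSE,
                           noise = noiseModel()) {
    stopifnot(nPatients >= 2, hazardRatio > 0)
    if (!is.null(censoring)) {
        if (length(censoring) != 2 || censoring[2] < censoring[1] ||
                censoring[1] < 0)
            stop("degenerate censoring window")
    }
    set.seed(as.integer(seed))
    poly <- stats::runif(nPatients) < polyProb
    # guarantee both groups are represented
    if (!any(poly)) poly[1] <- TRUE
    if (all(poly)) poly[1] <- FALSE
    cc <- integer(nPatients)
    cc[poly] <- sample(c(1L, 2L, 3L, 4L), sum(poly), replace = TRUE,
                       prob = c(46, 11, 1, 1) / 59)
    coo <- sample(c("GCB", "ABC", "Unclassified", NA), nPatients,
                  replace = TRUE, prob = c(30, 35, 8, 1) / 74)

    hEfs <- baseHazard * ifelse(poly, hazardRatio, 1)
    hOs <- baseOsHazard * ifelse(poly, osHazardRatio, 1)
    tEfs <- stats::rexp(nPatients, hEfs)
    tOs <- stats::rexp(nPatients, hOs)
    if (is.null(censoring)) {
        cens <- rep(Inf, nPatients)
    } else {
        cens <- stats::runif(nPatients, censoring[1], censoring[2])
    }
    clinical <- data.frame(
        patient_id = sprintf("P%04d", seq_len(nPatients)),
        cc = cc,
        cc_class = ifelse(poly, "Poly", "Mono"),
        coo = coo,
        efs_days = pmin(tEfs, cens),
        efs_event = as.integer(tEfs <= cens),
        os_days = pmin(tOs, cens),
        os_event = as.integer(tOs <= cens),
        stage = sample(c("III", "IV"), nPatients, replace = TRUE,
                       prob = c(20, 54) / 74),
        therapy = sample(c("R-CHOP", "R-THPCOP", "R-CVP"), nPatients,
                         replace = TRUE, prob = c(52, 21, 1) / 74),
        extranodal_count = stats::rpois(nPatients, ifelse(poly, 1.6, 1.2)),
        ki67_fraction = stats::rbeta(nPatients,
                                     ifelse(poly, 8, 6), ifelse(poly, 3, 4)),
        stringsAsFactors = FALSE)
    truth <- list(poly_prob = polyProb, hazard_ratio = hazardRatio,
                  cc = cc, cc_class = clinical$cc_class)
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        writeClinicalCsv(clinical, file.path(dir, "clinical.csv"))
        jsonlite::write_json(truth, file.path(dir, "truth.json"),
                             auto_unbox = TRUE, digits = NA, na = "null")
        if (renderProbes) {
            for (i in seq_len(nPatients)) {
                sim <- simulateSample(architectureForCC(min(cc[i], 3L)),
                                      noise, seed = seed + i,
                                      sampleId = clinical$patient_id[i])
                writeProbeTable(sim$probes,
                                file.path(dir, paste0(clinical$patient_id[i], ".tsv")))
            }
        }
    }
    list(clinical = clinical, truth = truth)
}

#' Read / write a clonal-architecture JSON description
#'
#' JSON with fields `purity`, `clones` (array of `clone_id`, `ccf`),
#' `events` (array of `chrom`, `start`, `end`, `n_total`, `n_minor`,
#' `clone_id`; 1-based inclusive bp) and optional `nested`.
#'
#' @param path File path.
#' @return `readArchitecture`: a [ClonalArchitecture-class].
#' @export
readArchitecture <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    clonalArchitecture(x$purity, as.data.frame(x$clones),
                       as.data.frame(x$events),
                       nested = isTRUE(x$nested))
}

#' @rdname readArchitecture
#' @param arch A [ClonalArchitecture-class].
#' @export
writeArchitecture <- function(arch, path) {
    stopifnot(is(arch, "ClonalArchitecture"))
    jsonlite::write_json(list(purity = arch@purity, clones = arch@clones,
                              events = arch@events, nested = arch@nested),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
}
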