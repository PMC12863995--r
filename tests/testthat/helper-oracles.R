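# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive everything from first principles and share
# no code with the package internals.

# two-sided Fisher p for a 2x2 table by full enumeration of the
# fixed-margin support (probability-mass rule)
oracleFisher2x2 <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    a <- max(0, c1 - r2):min(r1, c1)
    probs <- dhyper(a, r1, r2, c1)
    pObs <- dhyper(tab[1, 1], r1, r2, c1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumeration over all assignments of
# the pooled (tie-free) values to the two groups
oracleMannWhitney <- function(x, y) {
    nx <- length(x); ny <- length(y)
    pool <- c(x, y)
    stopifnot(!any(duplicated(pool)))
    uStat <- function(g1) sum(outer(pool[g1], pool[-g1], ">"))
    uObs <- uStat(seq_len(nx))
    mu <- nx * ny / 2
    idx <- utils::combn(nx + ny, nx)
    uAll <- apply(idx, 2, uStat)
    mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-9)
}

# brute-force (state, fraction) grid fit with inline mixture formulas
oracleFitSegment <- function(ml, mb, maxTotal = 4, wl = 1, wb = 4) {
    best <- NULL
    for (nT in 0:maxTotal) for (nB in 0:(nT %/% 2)) {
        if (nT == 2 && nB == 1) next
        for (f in seq(0.01, 1, by = 0.01)) {
            if (nT == 0 && f >= 1) next
            avg <- 2 * (1 - f) + f * nT
            r <- wl * (ml - log2(avg / 2))^2
            if (!is.na(mb)) {
                eb <- ((1 - f) + f * nB) / avg
                r <- r + wb * (mb - max(eb, 1 - eb))^2
            }
            cand <- list(nT = nT, nB = nB, f = f, res = r)
            if (is.null(best)) { best <- cand; next }
            if (r < best$res - 1e-12) { best <- cand; next }
            if (r <= best$res + 1e-12) {
                # ties: smaller |nT-2|, then larger nB, then smaller f
                keyNew <- c(abs(nT - 2), -nB, f)
                keyOld <- c(abs(best$nT - 2), -best$nB, best$f)
                cmp <- sign(keyNew - keyOld)
                first <- cmp[cmp != 0][1]
                if (!is.na(first) && first < 0) best <- cand
            }
        }
    }
    best
}

# minimum number of fraction clusters over all contiguous partitions of
# the sorted fits such that every member lies within delta of its
# cluster's length-weighted centroid; returns count and the centroids of
# the first minimal valid partition
oracleClusterPartitions <- function(f, w, delta) {
    o <- order(f)
    f <- f[o]; w <- w[o]
    n <- length(f)
    best <- NULL
    for (mask in 0:(2^(n - 1) - 1)) {
        cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
        bounds <- cbind(c(1, cuts + 1), c(cuts, n))
        valid <- TRUE
        centroids <- numeric(nrow(bounds))
        for (i in seq_len(nrow(bounds))) {
            j <- bounds[i, 1]:bounds[i, 2]
            centroids[i] <- sum(f[j] * w[j]) / sum(w[j])
            if (any(abs(f[j] - centroids[i]) > delta)) { valid <- FALSE; break }
        }
        if (valid && (is.null(best) || nrow(bounds) < length(best)))
            best <- centroids
    }
    best
}

# Newton iteration on the exact Cox partial likelihood for one binary
# covariate without ties
oracleCoxNewton <- function(time, event, x, iter = 30) {
    o <- order(time)
    time <- time[o]; event <- event[o]; x <- x[o]
    stopifnot(!any(duplicated(time[event == 1])))
    beta <- 0
    for (it in seq_len(iter)) {
        U <- 0; I <- 0
        for (i in which(event == 1)) {
            risk <- which(time >= time[i])
            w <- exp(beta * x[risk])
            s0 <- sum(w); s1 <- sum(x[risk] * w); s2 <- sum(x[risk]^2 * w)
            U <- U + x[i] - s1 / s0
            I <- I + s2 / s0 - (s1 / s0)^2
        }
        beta <- beta + U / I
    }
    beta
}

# hand-computable product-limit estimator
oracleKM <- function(time, event) {
    o <- order(time)
    time <- time[o]; event <- event[o]
    ts <- unique(time[event == 1])
    surv <- numeric(length(ts)); s <- 1
    for (i in seq_along(ts)) {
        atRisk <- sum(time >= ts[i])
        d <- sum(time == ts[i] & event == 1)
        s <- s * (1 - d / atRisk)
        surv[i] <- s
    }
    list(time = ts, surv = surv)
}
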