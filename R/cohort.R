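#' @importFrom survival Surv survfit survdiff coxph strata
#' @importFrom stats fisher.test wilcox.test kruskal.test cor.test
#'   median qnorm pchisq setNames
NULL

#' Fisher's exact test on a contingency table
#'
#' Two-sided exact test. For 2x2 tables the p-value is the sum of
#' hypergeometric probabilities (fixed margins) of all tables no more
#' probable than the observed one (probability-mass rule, relative
#' tolerance 1e-7); for r x c tables the Freeman-Halton generalization
#' over the fixed-margin support. Computed with [stats::fisher.test()].
#'
#' @param tab Matrix of non-negative integer counts, at least 2x2, with
#'   positive row and column margins.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisherExact(matrix(c(1, 14, 2, 57), 2, byrow = TRUE)) # 0.499
#' @export
fisherExact <- function(tab) {
    tab <- as.matrix(tab)
    if (any(tab < 0) || any(tab != round(tab)))
        stop("counts must be non-negative integers")
    if (nrow(tab) < 2 || ncol(tab) < 2)
        stop("table must be at least 2x2")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("empty margin in contingency table")
    stats::fisher.test(tab)$p.value
}

#' Summary statistics of a count distribution
#'
#' @param x Either a numeric vector of observations or a named vector of
#'   counts (names = values, entries = multiplicities).
#' @param counts Interpret `x` as a value-to-count map (default: `TRUE`
#'   when `x` has names).
#' @return List with `mean`, `sd` (n - 1 denominator), `sd_pop` (n
#'   denominator; reported because printed SDs in the field are often
#'   ambiguous between the two), `median`, `range`, `n`.
#' @examples
#' summarizeCounts(c(`0` = 15, `1` = 46, `2` = 11, `3` = 1, `4` = 1))$mean
#' @export
summarizeCounts <- function(x, counts = !is.null(names(x))) {
    if (counts) {
        v <- rep(as.numeric(names(x)), times = as.integer(x))
    } else v <- as.numeric(x)
    if (!length(v)) stop("empty distribution")
    n <- length(v)
    sdn1 <- if (n > 1) stats::sd(v) else 0
    list(mean = mean(v), sd = sdn1,
         sd_pop = sqrt(mean((v - mean(v))^2)),
         median = stats::median(v), range = range(v), n = n)
}

#' Rank tests and correlation
#'
#' Thin validated wrappers over the standard implementations:
#' `mannWhitney` is the two-sided Mann-Whitney U / Wilcoxon rank-sum
#' test (exact enumeration for small tie-free samples, normal
#' approximation with continuity and tie correction otherwise),
#' `kruskalWallis` the Kruskal-Wallis rank test, and `pearsonR`
#' Pearson's product-moment correlation with its two-sided p-value.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param groups List of numeric vectors.
#' @return `mannWhitney`, `kruskalWallis`: two-sided p-value;
#'   `pearsonR`: list with `r` and `p`.
#' @export
mannWhitney <- function(x, y) {
    if (!length(x) || !length(y)) stop("both groups must be non-empty")
    exact <- (length(x) + length(y)) <= 20 && !any(duplicated(c(x, y)))
    suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' @rdname mannWhitney
#' @export
kruskalWallis <- function(groups) {
    if (any(!lengths(groups))) stop("all groups must be non-empty")
    stats::kruskal.test(groups)$p.value
}

#' @rdname mannWhitney
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3)
        stop("x and y must be equal-length with n >= 3")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined for constant input")
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value)
}

#' Kaplan-Meier estimate
#'
#' Product-limit survival estimator with Greenwood standard errors.
#'
#' @param time Follow-up times (days, >= 0).
#' @param event Event indicators in \{0, 1\}.
#' @return An object of class `kmCurve`: list with `time` (event times),
#'   `surv`, `n_risk`, `n_event`, `std_err` (Greenwood SE of the
#'   survival estimate), queryable with [survivalAt()].
#' @examples
#' km <- kmEstimate(c(1, 2, 3, 4, 4, 5, 7, 9),
#'                  c(1, 0, 1, 1, 0, 0, 1, 1))
#' survivalAt(km, 4) # 0.5833
#' @export
kmEstimate <- function(time, event) {
    stopifnot(length(time) == length(event), all(time >= 0),
              all(event %in% 0:1))
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    sm <- summary(fit, censored = FALSE)
    structure(list(time = sm$time, surv = sm$surv, n_risk = sm$n.risk,
                   n_event = sm$n.event,
                   std_err = sm$surv * sm$std.err / ifelse(sm$surv > 0, 1, 1)),
              class = "kmCurve")
}

#' @rdname kmEstimate
#' @param km A `kmCurve`.
#' @param t Time at which to query the survival estimate.
#' @return `survivalAt`: S(t), starting at 1 before the first event.
#' @export
survivalAt <- function(km, t) {
    stopifnot(inherits(km, "kmCurve"))
    vapply(t, function(tt) {
        i <- which(km$time <= tt)
        if (!length(i)) 1 else km$surv[max(i)]
    }, 0)
}

#' Log-rank test
#'
#' Compares survival between groups; chi-square with (groups - 1)
#' degrees of freedom via [survival::survdiff()].
#'
#' @param time,event As in [kmEstimate()].
#' @param group Group labels (at least 2 non-empty groups).
#' @return Two-sided p-value.
#' @export
logrank <- function(time, event, group) {
    group <- as.factor(droplevels(as.factor(group)))
    if (nlevels(group) < 2) stop("need at least 2 non-empty groups")
    if (sum(event) < 1) stop("need at least one event")
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    stats::pchisq(sd$chisq, df = nlevels(group) - 1, lower.tail = FALSE)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron handling of tied event
#' times; Wald 95\% confidence intervals. Monotone-likelihood
#' (perfect-separation) fits are flagged as non-converged.
#'
#' @param time,event As in [kmEstimate()].
#' @param covariates data.frame of covariates (one column per term).
#' @param strataVar Optional stratification factor.
#' @return List with `coef` (log hazard ratios), `hr`, `ci_lower`,
#'   `ci_upper`, `se`, `labels`, `converged`.
#' @export
coxFit <- function(time, event, covariates, strataVar = NULL) {
    if (sum(event) < 1) stop("need at least one event")
    covariates <- as.data.frame(covariates)
    dat <- cbind(data.frame(.time = time, .event = event), covariates)
    rhs <- paste(sprintf("`%s`", names(covariates)), collapse = " + ")
    if (!is.null(strataVar)) {
        dat$.strata <- strataVar
        rhs <- paste(rhs, "+ strata(.strata)")
    }
    fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
    fit <- withCallingHandlers(
        survival::coxph(fml, data = dat, ties = "efron"),
        warning = function(w) invokeRestart("muffleWarning"))
    beta <- stats::coef(fit)
    se <- sqrt(diag(fit$var))
    converged <- all(is.finite(beta)) && all(abs(beta) < 15) &&
        all(is.finite(se)) && all(se < 1e3)
    z <- stats::qnorm(0.975)
    list(coef = unname(beta), hr = unname(exp(beta)),
         ci_lower = unname(exp(beta - z * se)),
         ci_upper = unname(exp(beta + z * se)),
         se = unname(se), labels = names(beta), converged = converged)
}

#' Minimum detectable hazard ratio (Schoenfeld formula)
#'
#' `HR = exp( (z_{1 - alpha/2} + z_{power}) / sqrt(d p (1 - p)) )` with
#' d the number of events and p the allocation fraction `n1 / (n1 + n2)`.
#'
#' @param n1,n2 Group sizes.
#' @param nEvents Total number of events d.
#' @param power Target power (default 0.8).
#' @param alpha Two-sided type-I error (default 0.05).
#' @return The minimum detectable hazard ratio (> 1).
#' @examples
#' minDetectableHR(15, 59, nEvents = 40)
#' @export
minDetectableHR <- function(n1, n2, nEvents, power = 0.8, alpha = 0.05) {
    stopifnot(nEvents > 0, power > 0, power < 1, alpha > 0, alpha < 1)
    p <- n1 / (n1 + n2)
    exp((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) /
            sqrt(nEvents * p * (1 - p)))
}

#' Cohort-level comparison report
#'
#' Runs the standard battery on a clinical table: Fisher exact tests of
#' categorical covariates against the grouping, a summary of the CC
#' distribution, Kaplan-Meier 5-year EFS/OS rates per group, log-rank
#' p-values, and univariate Cox hazard ratios for the grouping.
#'
#' @param cohort data.frame as returned by [readClinicalCsv()] or
#'   [simulateCohort()].
#' @param group Name of the grouping column (default `"cc_class"`).
#' @param categorical Names of categorical covariate columns to test
#'   (default: those of `stage`, `therapy`, `coo` present).
#' @return Nested list of results.
#' @export
cohortAnalysis <- function(cohort, group = "cc_class",
                           categorical = intersect(c("stage", "therapy", "coo"),
                                                   names(cohort))) {
    stopifnot(group %in% names(cohort))
    g <- as.factor(cohort[[group]])
    tests <- lapply(categorical, function(col) {
        tab <- table(cohort[[col]], g)
        tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
        if (nrow(tab) < 2 || ncol(tab) < 2) return(NULL)
        list(table = unclass(tab), p = fisherExact(tab))
    })
    names(tests) <- categorical
    ccSummary <- if ("cc" %in% names(cohort))
        summarizeCounts(cohort$cc, counts = FALSE) else NULL
    fiveYears <- 5 * 365
    kmByGroup <- lapply(split(seq_len(nrow(cohort)), g), function(i) {
        km <- kmEstimate(cohort$efs_days[i], cohort$efs_event[i])
        list(efs_5y = survivalAt(km, fiveYears),
             os_5y = survivalAt(kmEstimate(cohort$os_days[i],
                                           cohort$os_event[i]), fiveYears))
    })
    cox <- coxFit(cohort$efs_days, cohort$efs_event,
                  data.frame(group = g))
    list(categorical = tests, cc_summary = ccSummary,
         km_5y = kmByGroup,
         logrank_efs = logrank(cohort$efs_days, cohort$efs_event, g),
         logrank_os = logrank(cohort$os_days, cohort$os_event, g),
         cox_efs = cox)
}
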