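test_that("Fisher exact p-values reproduce the published cohort tables", {
    ref <- dlbclCohortCounts()
    expect_equal(fisherExact(ref$tables$ebv), 0.499, tolerance = 2e-3)
    expect_equal(fisherExact(ref$tables$ecog), 0.443, tolerance = 2e-3)
    expect_equal(fisherExact(ref$tables$extranodal), 0.773, tolerance = 2e-3)
    expect_equal(fisherExact(ref$tables$stage), 1.00, tolerance = 2e-3)
    expect_equal(fisherExact(ref$tables$therapy), 0.192, tolerance = 2e-3)
})

test_that("Fisher exact is label-invariant and validates its input", {
    tab <- matrix(c(3, 9, 14, 5), 2)
    p <- fisherExact(tab)
    expect_equal(fisherExact(tab[2:1, ]), p)
    expect_equal(fisherExact(tab[, 2:1]), p)
    expect_equal(fisherExact(t(tab)), p)
    expect_error(fisherExact(matrix(c(0, 0, 1, 2), 2)), "margin")
    expect_error(fisherExact(matrix(c(1.5, 1, 2, 2), 2)), "integer")
})

test_that("count summaries report both SD conventions", {
    ref <- dlbclCohortCounts()
    s <- summarizeCounts(ref$cc_counts)
    expect_equal(s$mean, 75 / 74, tolerance = 1e-12)
    expect_equal(s$median, 1)
    expect_equal(s$range, c(0, 4))
    expect_equal(s$sd, sd(rep(0:4, times = c(15, 46, 11, 1, 1))))
    expect_lt(s$sd_pop, s$sd)
    s5 <- summarizeCounts(c(`5` = 3))
    expect_equal(s5$mean, 5)
    expect_equal(s5$sd, 0)
    expect_error(summarizeCounts(numeric()), "empty")
})

test_that("rank tests behave at the null and reject bad input", {
    x <- c(1.2, 3.4, 2.2, 5.1, 0.4, 2.9)
    expect_gt(mannWhitney(x, x), 0.9)
    expect_error(mannWhitney(numeric(), 1:3), "non-empty")
    expect_error(kruskalWallis(list(1:3, numeric())), "non-empty")
    expect_equal(pearsonR(x, x)$r, 1, tolerance = 1e-12)
    expect_error(pearsonR(x, rep(2, 6)), "constant")
})

test_that("Kaplan-Meier estimates match the hand-computed product-limit table", {
    time <- c(1, 2, 3, 4, 4, 5, 7, 9)
    event <- c(1, 0, 1, 1, 0, 0, 1, 1)
    km <- kmEstimate(time, event)
    expect_equal(km$time, c(1, 3, 4, 7, 9))
    expect_equal(km$surv, c(7 / 8,
                            7 / 8 * 5 / 6,
                            7 / 8 * 5 / 6 * 4 / 5,
                            7 / 8 * 5 / 6 * 4 / 5 * 1 / 2,
                            0), tolerance = 1e-12)
    hand <- oracleKM(time, event)
    expect_equal(km$surv, hand$surv, tolerance = 1e-12)
    # no censoring: S(t) is the empirical survivor function
    t2 <- c(2, 5, 8, 1, 9, 4)
    km2 <- kmEstimate(t2, rep(1, 6))
    for (tt in c(0.5, 2, 4.5, 8.5, 10))
        expect_equal(survivalAt(km2, tt), mean(t2 > tt))
})

test_that("log-rank is symmetric in group labels and null on duplicates", {
    set.seed(21)
    time <- rexp(40); event <- rbinom(40, 1, 0.8)
    g <- rep(c("a", "b"), 20)
    p1 <- logrank(time, event, g)
    p2 <- logrank(time, event, ifelse(g == "a", "b", "a"))
    expect_equal(p1, p2, tolerance = 1e-12)
    # identical groups duplicated
    p <- logrank(c(time, time), c(event, event), rep(c("x", "y"), each = 40))
    expect_gt(p, 0.99)
    expect_error(logrank(time, rep(0, 40), g), "event")
})

test_that("Cox fit matches an exact Newton oracle and recovers the null", {
    time <- c(2, 5, 1, 7, 9, 4)
    event <- rep(1, 6)
    x <- c(1, 1, 0, 0, 1, 0)
    fit <- coxFit(time, event, data.frame(x = x))
    expect_equal(fit$coef, oracleCoxNewton(time, event, x), tolerance = 1e-6)
    expect_true(fit$converged)

    set.seed(33)
    coh <- simulateCohort(800, hazardRatio = 1, censoring = NULL, seed = 33)
    cl <- coh$clinical
    f0 <- coxFit(cl$efs_days, cl$efs_event,
                 data.frame(poly = as.integer(cl$cc_class == "Poly")))
    expect_lt(f0$ci_lower, 1)
    expect_gt(f0$ci_upper, 1)
    expect_true(f0$ci_lower <= f0$hr && f0$hr <= f0$ci_upper)
})

test_that("perfect separation is flagged as non-convergence", {
    time <- c(1, 2, 3, 10, 11, 12)
    event <- rep(1, 6)
    x <- c(1, 1, 1, 0, 0, 0)  # all early events in one group
    fit <- coxFit(time, event, data.frame(x = x))
    expect_false(fit$converged)
})

test_that("minimum detectable HR follows the Schoenfeld scaling laws", {
    h1 <- minDetectableHR(15, 59, nEvents = 40)
    h2 <- minDetectableHR(15, 59, nEvents = 80)
    expect_equal(log(h2), log(h1) / sqrt(2), tolerance = 1e-12)
    # z-terms cancel: HR -> 1
    expect_equal(minDetectableHR(10, 10, 50, power = 0.5, alpha = 1 - 1e-12),
                 1, tolerance = 1e-5)
    # balanced allocation is most efficient
    expect_lt(minDetectableHR(50, 50, 60), minDetectableHR(20, 80, 60))
    expect_error(minDetectableHR(10, 10, 0), "nEvents")
})

test_that("cohort analysis assembles the comparison battery", {
    coh <- simulateCohort(150, seed = 44)
    out <- cohortAnalysis(coh$clinical)
    expect_true(all(c("categorical", "cc_summary", "km_5y",
                      "logrank_efs", "cox_efs") %in% names(out)))
    expect_true(out$logrank_efs >= 0 && out$logrank_efs <= 1)
    expect_equal(sort(names(out$km_5y)), c("Mono", "Poly"))
    for (tst in Filter(Negate(is.null), out$categorical))
        expect_true(tst$p > 0 && tst$p <= 1)
    expect_equal(out$cc_summary$n, 150L)
})
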