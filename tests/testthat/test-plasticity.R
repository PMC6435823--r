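makePaired <- function(baseline, after, group = "treated") {
    new("PairedIntensityTable",
        table = data.frame(punctum_id = seq_along(baseline),
                           baseline = baseline, after_raw = after,
                           after_corrected = after,
                           delta = after - baseline),
        correctionFactor = NA_real_, group = group)
}

test_that("vehicle correction divides by the mean vehicle after/before ratio", {
    tr <- makePaired(c(100, 50), c(90, 45))
    veh <- makePaired(c(10, 20, 30), c(9, 18, 27), "vehicle")
    out <- vehicleCorrect(tr, veh)
    expect_equal(out@correctionFactor, 0.9)
    expect_equal(azTable(out)$after_corrected, c(100, 50))
    # identity vehicle leaves treated unchanged
    veh1 <- makePaired(c(5, 6), c(5, 6), "vehicle")
    expect_equal(azTable(vehicleCorrect(tr, veh1))$after_corrected,
                 c(90, 45))
    expect_error(vehicleCorrect(tr, makePaired(numeric(0), numeric(0))),
                 "empty")
    expect_error(vehicleCorrect(tr, makePaired(c(0, 1), c(1, 1))),
                 "positive")

    # exact inverse of the generator's vehicle drift when noise is off
    m <- simulateAZMap(40, seed = 51)
    p <- simulatePairedIntensities(m, "null", noiseCV = 0,
                                   vehicleDrift = 1.25, seed = 52)
    out2 <- vehicleCorrect(p$treated, p$vehicle)
    expect_equal(azTable(out2)$after_corrected, azTable(p$treated)$baseline,
                 tolerance = 1e-12)
})

test_that("paired change test gates on normality and handles degeneracy", {
    z <- makePaired(rep(10, 8), rep(10, 8))
    res <- pairedChangeTest(z)
    expect_equal(res$test, "degenerate")
    expect_equal(res$p.value, 1)

    set.seed(53)
    d <- 5 + rnorm(20, 0, 0.01)
    big <- makePaired(rep(100, 20), 100 + d)
    res2 <- pairedChangeTest(big)
    expect_lt(res2$p.value, 0.001)
    expect_equal(res2$test, "paired t")
    # oracle: closed-form t statistic on the deltas
    tOracle <- mean(d) / (sd(d) / sqrt(20))
    expect_equal(res2$statistic, tOracle, tolerance = 1e-9)

    expect_error(pairedChangeTest(makePaired(1:3, 2:4)), ">= 6")
})

test_that("scaling fit recovers exact additive and multiplicative truth", {
    b <- c(10, 20, 30, 40, 55)
    fm <- fitScalingModels(makePaired(b, 2 * b))
    expect_equal(selectedModel(fm), "multiplicative")
    expect_equal(fm@multiplicativeM, 2)
    expect_equal(fm@rssMult, 0, tolerance = 1e-20)
    expect_equal(fm@freeSlope, 2, tolerance = 1e-12)
    expect_equal(fm@freeIntercept, 0, tolerance = 1e-9)
    expect_equal(fm@rSquared, 1)

    fa <- fitScalingModels(makePaired(b, b + 5))
    expect_equal(selectedModel(fa), "additive")
    expect_equal(fa@additiveC, 5)
    expect_equal(fa@rssAdd, 0, tolerance = 1e-20)

    # y = x exactly satisfies both one-parameter models
    fi <- fitScalingModels(makePaired(b, b))
    expect_equal(selectedModel(fi), "indistinguishable")

    expect_error(fitScalingModels(makePaired(c(1, 1, 1), c(2, 2, 2))),
                 "variance")
    expect_error(fitScalingModels(makePaired(1:2, 2:3)), ">= 3")
})

test_that("scaling fit on simulated multiplicative data recovers the factor", {
    m <- simulateAZMap(500, seed = 54)
    p <- simulatePairedIntensities(m, "multiplicative", 1.16,
                                   noiseCV = 0.1, seed = 11)
    out <- vehicleCorrect(p$treated, p$vehicle)
    f <- fitScalingModels(out)
    expect_equal(selectedModel(f), "multiplicative")
    # free OLS slope within 5% of the planted 1.16
    expect_lt(abs(f@freeSlope - 1.16) / 1.16, 0.05)
    # oracle: closed-form OLS on the same numbers
    tb <- azTable(out)
    slopeOracle <- cov(tb$baseline, tb$after_corrected) / var(tb$baseline)
    expect_equal(f@freeSlope, slopeOracle, tolerance = 1e-12)
})

test_that("tercile analysis splits by rank and matches Fisher enumeration", {
    # all increases: proportions 0 and all p = 1
    up <- makePaired(1:12, (1:12) + 1)
    rep1 <- tercileChangeAnalysis(up)
    expect_equal(azTable(rep1)$prop_nochange, c(0, 0, 0))
    expect_equal(rep1@fisher$p.value, rep(1, 3))
    expect_equal(azTable(rep1)$n, c(4L, 4L, 4L))

    # n = 9 -> three per tercile
    expect_equal(azTable(tercileChangeAnalysis(
        makePaired(9:1, (9:1) + 1)))$n, c(3L, 3L, 3L))
    expect_error(tercileChangeAnalysis(makePaired(1:8, 1:8)), ">= 9")

    # 8/17 vs 2/17 worked example against hypergeometric enumeration
    pEnum <- fisherEnumOracle(8, 9, 2, 15)
    expect_equal(fisher.test(matrix(c(8, 9, 2, 15), 2,
                                    byrow = TRUE))$p.value,
                 pEnum, tolerance = 1e-9)

    # the report's own pairwise p-values match enumeration
    set.seed(55)
    pi <- makePaired(runif(30, 1, 100), runif(30, 1, 100) + rnorm(30))
    rp <- tercileChangeAnalysis(pi)
    cnt <- azTable(rp)$n_nochange
    n <- azTable(rp)$n
    pairs <- list(c(1, 2), c(2, 3), c(1, 3))
    for (i in 1:3) {
        a <- cnt[pairs[[i]][1]]; c2 <- cnt[pairs[[i]][2]]
        expect_equal(rp@fisher$p.value[i],
                     fisherEnumOracle(a, n[pairs[[i]][1]] - a,
                                      c2, n[pairs[[i]][2]] - c2),
                     tolerance = 1e-9)
    }
})

test_that("population comparison normalizes to control and gates tests", {
    set.seed(56)
    ctrl <- rnorm(14, 100, 5)
    res <- populationCompare(list(control = ctrl, same = ctrl),
                             normalizeTo = "control")
    sm <- res$summary
    expect_equal(sm$normalized_mean[sm$group == "same"],
                 mean(ctrl) / mean(ctrl))
    expect_gt(sm$p.value[sm$group == "same"], 0.9)

    # a 1.36x group is recovered within 3 SE
    treated <- 136 * (1 + rnorm(14, 0, 0.05))
    res2 <- populationCompare(list(control = ctrl, php = treated),
                              normalizeTo = "control")
    row <- res2$summary[res2$summary$group == "php", ]
    expect_lt(abs(row$normalized_mean - 1.36), 3 * row$normalized_sem)
    expect_lt(row$p.value, 0.001)

    expect_error(populationCompare(list(a = 1:5), "a"), "two groups")
    expect_error(populationCompare(list(a = 1:5, b = 2), "a"), ">= 3")
    expect_error(populationCompare(list(a = 1:5, b = 1:5), "zzz"),
                 "unknown control")

    # cumulative distributions are emitted per AZ when requested
    res3 <- populationCompare(list(control = ctrl, php = treated),
                              normalizeTo = "control",
                              perAZ = list(control = rnorm(50, 100, 20),
                                           php = rnorm(50, 140, 20)))
    expect_true(!is.null(res3$cdf))
    expect_equal(max(res3$cdf$cumulative), 1)
})

test_that("scaling-model selection is reliable across replicates", {
    nRep <- 40
    okM <- okA <- logical(nRep)
    for (s in seq_len(nRep)) {
        m <- simulateAZMap(500, seed = 1000 + s)
        meanB <- mean(azTable(m)$true_level)
        pm <- simulatePairedIntensities(m, "multiplicative", 1.5,
                                        noiseCV = 0.1, seed = 2000 + s)
        pa <- simulatePairedIntensities(m, "additive", 0.5 * meanB,
                                        noiseCV = 0.1, seed = 3000 + s)
        okM[s] <- selectedModel(fitScalingModels(
            vehicleCorrect(pm$treated, pm$vehicle))) == "multiplicative"
        okA[s] <- selectedModel(fitScalingModels(
            vehicleCorrect(pa$treated, pa$vehicle))) == "additive"
    }
    expect_gte(mean(okM), 0.95)
    expect_gte(mean(okA), 0.95)
})
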