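test_that("AZ map generation respects spacing, clamping and determinism", {
    m1 <- simulateAZMap(100, seed = 7)
    m2 <- simulateAZMap(100, seed = 7)
    expect_identical(azTable(m1), azTable(m2))
    tb <- azTable(m1)
    d <- as.matrix(dist(tb[, c("x", "y")]))
    diag(d) <- Inf
    expect_gte(min(d), 5)
    expect_true(all(tb$true_pr >= 0.001 & tb$true_pr <= 1))
    expect_true(all(tb$true_level > 0))

    one <- azTable(simulateAZMap(1, seed = 7))
    expect_equal(nrow(one), 1)
    expect_gte(one$true_pr, 0.001)
    expect_lte(one$true_pr, 1)

    # infeasible placement errors out rather than looping forever
    expect_error(simulateAZMap(400, fieldWidth = 40, fieldHeight = 40,
                               minSpacing = 10, seed = 1),
                 "could not place")
})

test_that("noise-free coupling makes Pr rank order follow level rank order", {
    m <- simulateAZMap(60, couplingNoiseSD = 0, seed = 3)
    tb <- azTable(m)
    expect_identical(order(tb$true_pr), order(tb$true_level))
})

test_that("second channel correlates with the first at the target r", {
    m <- simulateAZMap(2000, fieldWidth = 1200, fieldHeight = 1200,
                       secondChannelR = 0.95, seed = 11)
    tb <- azTable(m)
    expect_equal(cor(tb$true_level, tb$second_level), 0.95,
                 tolerance = 0.03)
})

test_that("generated Pr median matches a Monte-Carlo oracle", {
    # oracle: independent re-implementation of the coupling (gamma draws,
    # min-max normalization, clamped affine map) over many replicate maps
    set.seed(99)
    meds <- replicate(2000, {
        lv <- rgamma(100, 2, 1)
        z <- (lv - min(lv)) / diff(range(lv))
        median(pmin(pmax(0.5 * z + rnorm(100, 0, 0.06), 0.001), 1))
    })
    oracle <- mean(meds)
    spread <- sd(meds)
    m <- simulateAZMap(100, seed = 1)
    expect_lt(abs(median(azTable(m)$true_pr) - oracle), 4 * spread)
})

test_that("rendered image integrates to the planted level", {
    m <- simulateAZMap(1, seed = 4)
    img <- pixels(renderPunctaImage(m, psfSigma = 1.5, background = 10,
                                    gain = 200, noise = "none"))
    L <- azTable(m)$true_level * 200
    expect_equal(sum(img) - 10 * length(img), L, tolerance = 0.01 * L)
    # argmax at the rounded center
    pk <- which(img == max(img), arr.ind = TRUE)
    expect_equal(unname(pk[1, "col"]) - 1, round(azTable(m)$x))
    expect_equal(unname(pk[1, "row"]) - 1, round(azTable(m)$y))

    # empty map renders constant background
    m0 <- simulateAZMap(2, seed = 5)
    m0@table <- m0@table[0, ]
    img0 <- pixels(renderPunctaImage(m0, background = 7, noise = "none"))
    expect_true(all(img0 == 7))
})

test_that("image total intensity is linear in AZ levels (noise off)", {
    m <- simulateAZMap(20, seed = 6)
    m2 <- m
    m2@table$true_level <- 2 * m2@table$true_level
    i1 <- pixels(renderPunctaImage(m, background = 0, noise = "none"))
    i2 <- pixels(renderPunctaImage(m2, background = 0, noise = "none"))
    expect_equal(sum(i2), 2 * sum(i1), tolerance = 1e-9)
})

test_that("release trials are Bernoulli with the planted Pr", {
    m <- simulateAZMap(10, seed = 8)
    # degenerate ends
    m0 <- m; m0@table$true_pr[] <- 0.001
    m1 <- m; m1@table$true_pr[] <- 1
    ev1 <- azTable(simulateReleaseTrials(m1, 5, jitterSD = 0, seed = 1))
    expect_equal(nrow(ev1), 50)
    expect_equal(sort(unique(ev1$stimulus)), 0:4)
    expect_equal(ev1$x[order(ev1$stimulus, ev1$true_az)],
                 rep(azTable(m)$x, 5))

    # binomial mean/variance over seeds for one AZ at Pr 0.11
    ms <- simulateAZMap(1, seed = 9)
    ms@table$true_pr <- 0.11
    counts <- vapply(1:400, function(s)
        nrow(azTable(simulateReleaseTrials(ms, 100, seed = s))), numeric(1))
    se <- sqrt(100 * 0.11 * 0.89 / 400)
    expect_lt(abs(mean(counts) - 11), 3 * se)
    expect_lt(abs(var(counts) - 100 * 0.11 * 0.89),
              3 * 100 * 0.11 * 0.89 * sqrt(2 / 399))
})

test_that("event movie flashes decay geometrically at the planted ratio", {
    m <- simulateAZMap(1, seed = 10)
    tb <- azTable(m)
    ev <- new("EventStream",
              events = data.frame(stimulus = 0L, x = round(tb$x),
                                  y = round(tb$y)),
              nStimuli = 1L)
    mov <- renderEventMovie(ev, m, nBaselineFrames = 3, framesPerStim = 6,
                            flashAmplitude = 40, decayRatio = 0.6,
                            decayFrames = 5, background = 2, noiseSD = 0,
                            seed = 1)
    f0 <- mov@stimFrames[1]
    px <- round(tb$x) + 1; py <- round(tb$y) + 1
    for (k in 0:4)
        expect_equal(mov@frames[[f0 + k]][py, px] - 2, 40 * 0.6^k,
                     tolerance = 1e-9)
    # baseline frames are flat
    expect_true(all(mov@frames[[1]] == 2))
    # no events -> all frames flat
    ev0 <- new("EventStream",
               events = data.frame(stimulus = integer(0), x = numeric(0),
                                   y = numeric(0)),
               nStimuli = 1L)
    mov0 <- renderEventMovie(ev0, m, noiseSD = 0, seed = 1)
    expect_true(all(vapply(mov0@frames, function(f) all(f == 5), logical(1))))
})

test_that("paired-intensity generator honours its perturbation modes", {
    m <- simulateAZMap(50, seed = 12)
    base <- azTable(m)$true_level

    pn <- simulatePairedIntensities(m, "null", noiseCV = 0, seed = 1)
    expect_equal(azTable(pn$treated)$after_raw, base)

    pm <- simulatePairedIntensities(m, "multiplicative", 2, noiseCV = 0,
                                    seed = 1)
    expect_equal(azTable(pm$treated)$after_raw, 2 * base)
    # multiplicative truth: after/before constant across AZs (noise off)
    expect_equal(var(azTable(pm$treated)$after_raw / base), 0)

    pa <- simulatePairedIntensities(m, "additive", 10, noiseCV = 0.05,
                                    seed = 3)
    d <- azTable(pa$treated)$after_raw - base
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - 10), 3 * se)

    expect_error(simulatePairedIntensities(m, "multiplicative", -1),
                 "must be > 0")
})

test_that("transient generator hits its planted peak and tau", {
    rec <- simulateTransientRecording(restingR = 2, deltaR = 4.5,
                                      tau = 0.08, nSweeps = 1,
                                      trainRate = 0, noiseSD = 0)
    R <- ratioTrace(rec)$R
    expect_equal(max(R), 2 + 4.5, tolerance = 1e-12)
    s <- summarizeTransient(rec)
    expect_equal(s$tau, 0.08, tolerance = 1e-6)

    # noise averaging: 10 sweeps at 2% noise recover the peak within 5%
    recN <- simulateTransientRecording(deltaR = 4.5, noiseSD = 0.02 * 4.5,
                                       nSweeps = 10, trainRate = 0,
                                       seed = 5)
    sN <- summarizeTransient(recN)
    expect_lt(abs(sN$deltaR - 4.5) / 4.5, 0.05)
})

test_that("ephys generator matches its quantal parameters", {
    r0 <- simulateEphysRecording(mejpCV = 0, mejpMean = 1.2, seed = 2)
    expect_true(all(r0@mejpAmplitudes == 1.2))
    expect_error(simulateEphysRecording(nMEJPs = 0), "nMEJPs")

    qc <- vapply(1:30, function(s)
        quantalContent(simulateEphysRecording(quantalContent = 30,
                                              mejpMean = 1, nMEJPs = 300,
                                              nEJPs = 40,
                                              seed = s))$quantal_content,
        numeric(1))
    expect_lt(abs(mean(qc) - 30), 3 * sd(qc) / sqrt(30))
})

test_that("generators are bit-reproducible at a fixed seed", {
    m <- simulateAZMap(30, seed = 21)
    expect_identical(pixels(renderPunctaImage(m, seed = 2)),
                     pixels(renderPunctaImage(m, seed = 2)))
    expect_identical(azTable(simulateReleaseTrials(m, 50, seed = 3)),
                     azTable(simulateReleaseTrials(m, 50, seed = 3)))
    a <- simulateTransientRecording(noiseSD = 0.1, seed = 4)
    b <- simulateTransientRecording(noiseSD = 0.1, seed = 4)
    expect_identical(a@rhod, b@rhod)
})
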