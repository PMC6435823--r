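test_that("preprocessing subtracts background and matches a convolution oracle", {
    flat <- matrix(5, 16, 16)
    out <- preprocessImage(flat, gaussianSigma = 0,
                           backgroundMethod = "constant",
                           backgroundValue = 5)
    expect_true(all(out == 0))
    # sigma 0, no background: identity
    img <- matrix(runif(64), 8, 8)
    expect_identical(preprocessImage(img, gaussianSigma = 0), img)
    expect_error(preprocessImage(matrix(c(1, NA, 1, 1), 2, 2)),
                 "non-finite")

    # impulse response equals the directly convolved Gaussian kernel
    imp <- matrix(0, 31, 31)
    imp[16, 16] <- 1
    sm <- preprocessImage(imp, gaussianSigma = 0.75)
    expect_equal(sm, directGaussianBlur(imp, 0.75), tolerance = 1e-5)
})

test_that("maxima finding isolates peaks and applies tolerance merging", {
    expect_equal(nrow(findMaxima(matrix(3, 20, 20), noiseTolerance = 1)), 0)

    # single noiseless spot: the argmax pixel
    m <- simulateAZMap(1, seed = 31)
    m@table$x <- 20; m@table$y <- 30
    img <- pixels(renderPunctaImage(m, background = 0, noise = "none"))
    mx <- findMaxima(img, noiseTolerance = 0.1, minIntensity = 0.5)
    expect_equal(nrow(mx), 1)
    expect_equal(c(mx$x, mx$y), c(20, 30))

    # two spots 12 px apart, tolerance below the dip depth: both found;
    # tolerance above it: merged into one
    m2 <- simulateAZMap(1, seed = 31)
    m2@table <- rbind(m2@table, m2@table)
    m2@table$az_id <- 1:2
    m2@table$x <- c(30, 42); m2@table$y <- c(32, 32)
    m2@table$true_level <- c(2, 2)
    img2 <- pixels(renderPunctaImage(m2, psfSigma = 1.5, background = 0,
                                     noise = "none"))
    # 1-D profile oracle for the dip depth between the two equal peaks
    prof <- img2[33, ]
    pk <- max(prof)
    dip <- min(prof[31:43])
    mx2 <- findMaxima(img2, noiseTolerance = 0.5 * (pk - dip),
                      minIntensity = 0.1)
    expect_equal(nrow(mx2), 2)
    expect_setequal(mx2$x, c(30, 42))
    # spots close enough to overlap: a tolerance above the (shallow) dip
    # merges them into one reported maximum
    m3 <- m2
    m3@table$x <- c(30, 34)
    img3 <- pixels(renderPunctaImage(m3, psfSigma = 1.5, background = 0,
                                     noise = "none"))
    prof3 <- img3[33, ]
    pk3 <- max(prof3)
    dip3 <- pk3 - min(prof3[31:35])
    mx1 <- findMaxima(img3, noiseTolerance = 1.5 * dip3,
                      minIntensity = 0.1)
    expect_equal(nrow(mx1), 1)
    mxBoth <- findMaxima(img3, noiseTolerance = 0.5 * dip3,
                         minIntensity = 0.1)
    expect_equal(nrow(mxBoth), 2)

    # plateau: single representative at the smallest (y, x)
    plat <- matrix(0, 10, 10)
    plat[4:5, 6:7] <- 2
    mp <- findMaxima(plat, noiseTolerance = 0.5, minIntensity = 1)
    expect_equal(nrow(mp), 1)
    expect_equal(c(mp$x, mp$y), c(5, 3))
})

test_that("segmentation partitions above-threshold pixels among maxima", {
    m <- simulateAZMap(6, fieldWidth = 96, fieldHeight = 96,
                       minSpacing = 20, levelOffset = 1, seed = 33)
    img <- pixels(renderPunctaImage(m, background = 0, noise = "none"))
    mx <- findMaxima(img, noiseTolerance = 1, minIntensity = 0.5)
    lab <- segmentPuncta(img, mx, minIntensity = 0.5)
    expect_equal(sort(unique(lab[lab > 0])), seq_len(nrow(mx)))
    # labels tile exactly the thresholded set
    expect_identical(lab > 0, img >= 0.5)
    # each maximum carries its own label
    expect_equal(lab[cbind(mx$y + 1, mx$x + 1)], seq_len(nrow(mx)))
    # well-separated spots resolve to the nearest maximum
    own <- apply(which(lab > 0, arr.ind = TRUE), 1, function(rc) {
        d <- (mx$x - (rc[2] - 1))^2 + (mx$y - (rc[1] - 1))^2
        which.min(d)
    })
    expect_equal(unname(lab[lab > 0]), unname(own))

    expect_error(segmentPuncta(img, data.frame(x = 1, y = 1),
                               minIntensity = 5),
                 "below minIntensity")
    lab0 <- segmentPuncta(img, data.frame(x = numeric(0), y = numeric(0)),
                          minIntensity = 0.5)
    expect_true(all(lab0 == 0))
})

test_that("punctum measurement reports area, centroid, mean and sum", {
    img <- matrix(0, 12, 12)
    img[3:5, 4:6] <- 7
    lab <- matrix(0L, 12, 12)
    lab[3:5, 4:6] <- 1L
    lab[9:10, 9] <- 2L
    img[9:10, 9] <- c(2, 4)
    pt <- azTable(measurePuncta(img, lab))
    expect_equal(nrow(pt), 2)
    expect_equal(pt$punctum_id, 1:2)
    expect_equal(pt$area, c(9L, 2L))
    expect_equal(pt$mean_intensity, c(7, 3))
    expect_equal(pt$sum_intensity, c(63, 6))
    expect_equal(pt$x[1], 4)  # uniform block centred on cols 4:6 -> x = 4
    expect_equal(pt$y[1], 3)
    expect_error(measurePuncta(img[1:6, ], lab), "shapes differ")
})

test_that("thresholded sum recovers the planted integrated intensity", {
    m <- simulateAZMap(1, seed = 35)
    img <- pixels(renderPunctaImage(m, psfSigma = 1.5, background = 0,
                                    gain = 200, noise = "none"))
    L <- azTable(m)$true_level * 200
    thr <- 0.01 * max(img)
    mx <- findMaxima(img, noiseTolerance = thr, minIntensity = thr)
    lab <- segmentPuncta(img, mx, minIntensity = thr)
    pt <- azTable(measurePuncta(img, lab))
    expect_equal(pt$sum_intensity, L, tolerance = 0.05 * L)
})

test_that("mask transfer keeps punctum geometry identical across targets", {
    m <- simulateAZMap(3, fieldWidth = 64, fieldHeight = 64,
                       minSpacing = 18, levelOffset = 1, seed = 36)
    img <- pixels(renderPunctaImage(m, background = 0, noise = "none"))
    res <- maskTransferMeasure(img, targets = list(same = img,
                                                   double = 2 * img),
                               noiseTolerance = 1, minIntensity = 0.5)
    direct <- detectPuncta(img, noiseTolerance = 1, minIntensity = 0.5)
    expect_equal(azTable(res$same), azTable(direct$puncta))
    expect_equal(azTable(res$double)$sum_intensity,
                 2 * azTable(res$same)$sum_intensity)

    # dimming one spot in the target reduces only its sum
    tb <- azTable(m)
    dimmed <- m
    mid <- order(tb$x)[2]
    dimmed@table$true_level[mid] <- 0.25 * tb$true_level[mid]
    imgD <- pixels(renderPunctaImage(dimmed, background = 0,
                                     noise = "none"))
    resD <- maskTransferMeasure(img, targets = list(d = imgD),
                                noiseTolerance = 1, minIntensity = 0.5)
    ptS <- azTable(res$same); ptD <- azTable(resD$d)
    expect_equal(nrow(ptD), 3)
    iMid <- which.min(abs(ptS$x - tb$x[mid]))
    ratio <- ptD$sum_intensity / ptS$sum_intensity
    expect_equal(ratio[iMid], 0.25, tolerance = 0.02)
    expect_equal(ratio[-iMid], c(1, 1), tolerance = 0.02)

    expect_error(maskTransferMeasure(img, targets = list(bad = img[1:10, ]),
                                     noiseTolerance = 1, minIntensity = 0.5),
                 "shape differs")
})

test_that("detection is accurate on noisy fields and noiseless centroids are sharp", {
    met <- lapply(1:5, function(s) {
        m <- simulateAZMap(100, levelOffset = 0.5, seed = s)
        img <- renderPunctaImage(m, noise = "gaussian", noiseSD = 2,
                                 seed = s + 500)
        d <- detectPuncta(img, backgroundMethod = "constant",
                          backgroundValue = 10)
        matchDetections(d$puncta, m)
    })
    expect_gte(mean(vapply(met, `[[`, 1, "recall")), 0.95)
    expect_gte(mean(vapply(met, `[[`, 1, "precision")), 0.95)

    m <- simulateAZMap(50, levelOffset = 0.5, seed = 77)
    img <- renderPunctaImage(m, noise = "none")
    d <- detectPuncta(img, backgroundMethod = "constant",
                      backgroundValue = 10, minIntensity = 1)
    met0 <- matchDetections(d$puncta, m)
    expect_lte(met0$centroidError, 0.5)
})
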