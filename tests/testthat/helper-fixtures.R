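# shared fixtures and independent oracles used across test files

# match detections to planted truth within a radius; returns recall,
# precision and mean centroid error of matched pairs
matchDetections <- function(puncta, azmap, radius = 2) {
    tb <- azTable(puncta)
    tr <- azTable(azmap)
    d <- sqrt(outer(tb$x, tr$x, `-`)^2 + outer(tb$y, tr$y, `-`)^2)
    nnTruth <- apply(d, 2, min)     # per planted AZ
    nnDet <- apply(d, 1, min)       # per detection
    list(recall = mean(nnTruth <= radius),
         precision = mean(nnDet <= radius),
         centroidError = mean(nnTruth[nnTruth <= radius]))
}

# two-sided Fisher exact p by full enumeration of the 2x2 tables sharing
# the observed margins, from first principles (no dhyper / fisher.test)
fisherEnumOracle <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
    lo <- max(0, c1 - r2); hi <- min(r1, c1)
    probs <- vapply(lo:hi, function(k)
        choose(r1, k) * choose(r2, c1 - k) / choose(n, c1), numeric(1))
    pObs <- choose(r1, a) * choose(r2, c) / choose(n, c1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# direct (loop-based) 2-D convolution of an image with a centred Gaussian
# kernel, the oracle for impulse-response tests
directGaussianBlur <- function(img, sigma, radius = 2 * ceiling(3 * sigma)) {
    k1 <- dnorm(-radius:radius, 0, sigma)
    k <- outer(k1, k1)
    k <- k / sum(k)
    H <- nrow(img); W <- ncol(img)
    out <- matrix(0, H, W)
    for (r in seq_len(H)) for (c in seq_len(W)) {
        acc <- 0
        for (dr in -radius:radius) for (dc in -radius:radius) {
            rr <- r + dr; cc <- c + dc
            if (rr >= 1 && rr <= H && cc >= 1 && cc <= W)
                acc <- acc + img[rr, cc] * k[dr + radius + 1, dc + radius + 1]
        }
        out[r, c] <- acc
    }
    out
}

# brute-force nearest-neighbour assignment oracle
bruteForceAssign <- function(ex, ey, px, py) {
    vapply(seq_along(ex), function(i) {
        d <- sqrt((px - ex[i])^2 + (py - ey[i])^2)
        which(d == min(d))[1]
    }, integer(1))
}
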