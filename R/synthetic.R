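## Synthetic-data generators. Every generator takes an integer seed and is
## bit-reproducible: identical arguments and seed give identical output.

#' Simulate a ground-truth active-zone map
#'
#' Places \code{nAZ} active zones uniformly at random on the field subject to
#' a minimum pairwise spacing (rejection sampling), draws right-skewed channel
#' levels, a correlated second-channel level, and couples release probability
#' to channel level through a clamped affine map on the min-max-normalized
#' level.
#'
#' Channel levels are gamma distributed (right-skewed: most AZs carry
#' low-to-moderate channel levels, a minority high levels). True release
#' probability is \code{clamp(slope * z + noise, 0.001, 1)} where \code{z}
#' is the level normalized to [0, 1] across the map. With the defaults the
#' map reproduces the empirical regime of single-AZ optical quantal analysis
#' at the fly NMJ: median Pr near 0.11 with roughly 90 percent of AZs between
#' 0.01 and 0.5, and a truth-level intensity-Pr correlation near 0.8.
#'
#' @param nAZ number of active zones (>= 1).
#' @param fieldWidth,fieldHeight field size in pixels.
#' @param levelShape,levelScale shape and scale of the gamma level
#'   distribution.
#' @param levelOffset constant added to every level (a shifted gamma);
#'   0 by default, useful to impose a minimum spot brightness.
#' @param couplingSlope slope of the affine level-to-Pr coupling.
#' @param couplingNoiseSD SD of Gaussian noise added on the Pr scale.
#' @param secondChannelR target Pearson correlation between the two channel
#'   levels.
#' @param minSpacing minimum pairwise center distance in pixels.
#' @param margin border (px) kept free of centers so spots render fully
#'   inside the field.
#' @param pixelSize micrometres per pixel.
#' @param seed integer seed.
#' @return an \linkS4class{AZMap}.
#' @examples
#' m <- simulateAZMap(50, seed = 1)
#' summary(azTable(m)$true_pr)
#' @export
simulateAZMap <- function(nAZ, fieldWidth = 256, fieldHeight = 256,
                          levelShape = 2, levelScale = 1, levelOffset = 0,
                          couplingSlope = 0.5, couplingNoiseSD = 0.06,
                          secondChannelR = 0.95, minSpacing = 5,
                          margin = 6, pixelSize = 0.1, seed = 1) {
    stopifnot(nAZ >= 1, fieldWidth > 2 * margin, fieldHeight > 2 * margin)
    set.seed(seed)
    xs <- ys <- numeric(nAZ)
    placed <- 0L
    sinceLast <- 0L
    maxStall <- 5000L
    while (placed < nAZ) {
        if (sinceLast >= maxStall)
            stop("could not place ", nAZ, " centers at minSpacing ",
                 minSpacing, " (no progress after ", maxStall,
                 " rejected proposals); enlarge the field or reduce ",
                 "nAZ/minSpacing")
        px <- runif(1, margin, fieldWidth - 1 - margin)
        py <- runif(1, margin, fieldHeight - 1 - margin)
        if (placed == 0L ||
            min((xs[seq_len(placed)] - px)^2 +
                (ys[seq_len(placed)] - py)^2) >= minSpacing^2) {
            placed <- placed + 1L
            xs[placed] <- px
            ys[placed] <- py
            sinceLast <- 0L
        } else sinceLast <- sinceLast + 1L
    }
    raw <- rgamma(nAZ, shape = levelShape, scale = levelScale)
    level <- levelOffset + raw
    ## second channel shares the gamma component plus independent noise
    ## sized so that cor(level, second) ~ secondChannelR; both channels
    ## carry the same brightness offset
    sdl <- if (nAZ > 1) sd(raw) else levelScale
    noiseSD <- if (secondChannelR >= 1) 0 else
        sdl * sqrt(1 / secondChannelR^2 - 1)
    second <- levelOffset + pmax(raw + rnorm(nAZ, 0, noiseSD), 0.01 * raw)
    z <- if (nAZ > 1 && diff(range(level)) > 0)
        (level - min(level)) / diff(range(level)) else rep(0.5, nAZ)
    pr <- pmin(pmax(couplingSlope * z + rnorm(nAZ, 0, couplingNoiseSD),
                    0.001), 1)
    new("AZMap",
        table = data.frame(az_id = seq_len(nAZ), x = xs, y = ys,
                           true_level = level, second_level = second,
                           true_pr = pr),
        fieldWidth = fieldWidth, fieldHeight = fieldHeight,
        pixelSize = pixelSize, minSpacing = minSpacing,
        params = list(seed = seed, levelShape = levelShape,
                      levelScale = levelScale, couplingSlope = couplingSlope,
                      couplingNoiseSD = couplingNoiseSD,
                      secondChannelR = secondChannelR, margin = margin))
}

## render isotropic Gaussian spots into a matrix; amplitude scaled so the
## integrated (infinite-plane) intensity of a spot equals gain * level
renderSpots <- function(width, height, x, y, level, psfSigma, gain) {
    img <- matrix(0, nrow = height, ncol = width)
    if (!length(x)) return(img)
    w <- ceiling(4 * psfSigma)
    for (i in seq_along(x)) {
        cx <- x[i]; cy <- y[i]
        amp <- gain * level[i] / (2 * pi * psfSigma^2)
        cols <- max(1, floor(cx + 1 - w)):min(width, ceiling(cx + 1 + w))
        rows <- max(1, floor(cy + 1 - w)):min(height, ceiling(cy + 1 + w))
        gx <- exp(-((cols - 1 - cx)^2) / (2 * psfSigma^2))
        gy <- exp(-((rows - 1 - cy)^2) / (2 * psfSigma^2))
        img[rows, cols] <- img[rows, cols] + amp * outer(gy, gx)
    }
    img
}

#' Render a punctum image from an AZ map
#'
#' Forward model for a confocal projection: each AZ becomes an isotropic
#' 2-D Gaussian spot whose integrated intensity is proportional to its
#' channel level, on a constant background, with optional seeded noise.
#'
#' @param azMap an \linkS4class{AZMap}.
#' @param channel which channel level to render: "first" (the tagged
#'   channel) or "second" (the scaffold channel used for masks).
#' @param psfSigma Gaussian spot sigma in pixels (> 0).
#' @param background constant background level (a.u.).
#' @param gain integrated spot intensity per unit level.
#' @param noise "gaussian" read noise, "poisson" shot noise, or "none".
#' @param noiseSD SD of Gaussian read noise.
#' @param seed integer seed for the noise.
#' @return an \linkS4class{ImageFrame}.
#' @export
renderPunctaImage <- function(azMap, channel = c("first", "second"),
                              psfSigma = 1.2, background = 10, gain = 200,
                              noise = c("gaussian", "poisson", "none"),
                              noiseSD = 2, seed = 1) {
    channel <- match.arg(channel)
    noise <- match.arg(noise)
    stopifnot(psfSigma > 0)
    tb <- azTable(azMap)
    W <- azMap@fieldWidth; H <- azMap@fieldHeight
    if (nrow(tb) && (any(tb$x < 0 | tb$x > W - 1) ||
                     any(tb$y < 0 | tb$y > H - 1)))
        stop("AZ center outside field")
    lv <- if (channel == "first") tb$true_level else tb$second_level
    img <- renderSpots(W, H, tb$x, tb$y, lv, psfSigma, gain) + background
    if (noise != "none") {
        set.seed(seed)
        img <- switch(noise,
            gaussian = pmax(img + rnorm(length(img), 0, noiseSD), 0),
            poisson = matrix(rpois(length(img), pmax(img, 0)),
                             nrow = nrow(img)))
    }
    new("ImageFrame", pixels = img, pixelSize = azMap@pixelSize,
        channel = channel)
}

#' Simulate Bernoulli release trials
#'
#' For each stimulus and each AZ an event occurs independently with the AZ's
#' true release probability; the event coordinate is the AZ center plus
#' isotropic Gaussian localization jitter. Per-AZ event counts are therefore
#' Binomial(nStimuli, true_pr).
#'
#' @param azMap an \linkS4class{AZMap}.
#' @param nStimuli number of stimuli (>= 1).
#' @param jitterSD isotropic Gaussian jitter SD in pixels.
#' @param seed integer seed.
#' @return an \linkS4class{EventStream} (stimulus indices 0-based).
#' @export
simulateReleaseTrials <- function(azMap, nStimuli = 100, jitterSD = 1,
                                  seed = 1) {
    stopifnot(nStimuli >= 1)
    set.seed(seed)
    tb <- azTable(azMap)
    nAZ <- nrow(tb)
    fire <- matrix(runif(nAZ * nStimuli), nrow = nAZ) <= tb$true_pr
    idx <- which(fire, arr.ind = TRUE)
    if (nrow(idx)) {
        ## order by stimulus then AZ for a deterministic layout
        o <- order(idx[, 2], idx[, 1])
        idx <- idx[o, , drop = FALSE]
        ev <- data.frame(
            stimulus = as.integer(idx[, 2] - 1L),
            x = tb$x[idx[, 1]] + rnorm(nrow(idx), 0, jitterSD),
            y = tb$y[idx[, 1]] + rnorm(nrow(idx), 0, jitterSD),
            true_az = tb$az_id[idx[, 1]])
    } else {
        ev <- data.frame(stimulus = integer(0), x = numeric(0),
                         y = numeric(0), true_az = integer(0))
    }
    new("EventStream", events = ev, nStimuli = as.integer(nStimuli))
}

#' Render a stimulus-locked event movie
#'
#' Each event becomes a Gaussian flash appearing in its stimulus frame and
#' decaying geometrically over the following frames; baseline (non-stimulus)
#' frames precede the first stimulus.
#'
#' @param events an \linkS4class{EventStream}.
#' @param azMap the \linkS4class{AZMap} providing the field geometry.
#' @param frameRate frames per second.
#' @param nBaselineFrames baseline frames at the start of the movie.
#' @param framesPerStim frames per stimulus period; the first is the
#'   stimulus-locked frame.
#' @param flashAmplitude peak amplitude of a flash (a.u.).
#' @param flashSigma Gaussian flash sigma (px).
#' @param decayRatio per-frame geometric decay factor in (0, 1).
#' @param decayFrames number of post-stimulus frames over which a flash
#'   persists (>= 2, so detection's persistence rule can apply).
#' @param background constant baseline fluorescence.
#' @param noiseSD Gaussian noise SD, 0 for noiseless.
#' @param seed integer seed.
#' @return an \linkS4class{AZMovie}.
#' @export
renderEventMovie <- function(events, azMap, frameRate = 15.3,
                             nBaselineFrames = 10, framesPerStim = 5,
                             flashAmplitude = 50, flashSigma = 1.5,
                             decayRatio = 0.5, decayFrames = 4,
                             background = 5, noiseSD = 1, seed = 1) {
    stopifnot(decayFrames >= 2, decayRatio > 0, decayRatio < 1)
    W <- azMap@fieldWidth; H <- azMap@fieldHeight
    nStim <- nStimuli(events)
    nFrames <- nBaselineFrames + nStim * framesPerStim
    stimFrames <- as.integer(nBaselineFrames + (seq_len(nStim) - 1L) *
                             framesPerStim + 1L)
    ev <- azTable(events)
    set.seed(seed)
    frames <- vector("list", nFrames)
    base <- matrix(background, nrow = H, ncol = W)
    for (f in seq_len(nFrames)) frames[[f]] <- base
    if (nrow(ev)) {
        for (i in seq_len(nrow(ev))) {
            f0 <- stimFrames[ev$stimulus[i] + 1L]
            for (k in 0:(decayFrames - 1L)) {
                f <- f0 + k
                if (f > nFrames) break
                amp <- flashAmplitude * decayRatio^k
                ## flash rendered with peak amplitude amp
                frames[[f]] <- frames[[f]] +
                    renderSpots(W, H, ev$x[i], ev$y[i],
                                amp * 2 * pi * flashSigma^2, flashSigma, 1)
            }
        }
    }
    if (noiseSD > 0)
        for (f in seq_len(nFrames))
            frames[[f]] <- pmax(frames[[f]] +
                matrix(rnorm(H * W, 0, noiseSD), nrow = H), 0)
    new("AZMovie", frames = frames, frameRate = frameRate,
        stimFrames = stimFrames,
        baselineFrames = seq_len(nBaselineFrames),
        pixelSize = azMap@pixelSize)
}

#' Simulate paired before/after intensities
#'
#' Generates a treated and a vehicle-only \linkS4class{PairedIntensityTable}
#' under a chosen perturbation: "null" (after = before), "additive"
#' (after = before + param) or "multiplicative" (after = param * before).
#' Multiplicative measurement noise with coefficient of variation
#' \code{noiseCV} and a shared multiplicative \code{vehicleDrift} (imaging
#' drift affecting treated and vehicle alike) are applied on top. The
#' vehicle group is drawn from an independent AZ map with the same level
#' distribution (vehicle animals are different preparations).
#'
#' @param azMap treated-group \linkS4class{AZMap}; its true levels are the
#'   baselines.
#' @param mode "null", "additive" or "multiplicative".
#' @param param offset c (a.u.) for additive, factor m (> 0) for
#'   multiplicative; ignored for null.
#' @param noiseCV coefficient of variation of multiplicative measurement
#'   noise (>= 0).
#' @param vehicleDrift multiplicative drift applied to both groups.
#' @param nVehicleAZ vehicle group size.
#' @param seed integer seed.
#' @return list with elements \code{treated} and \code{vehicle}, both
#'   \linkS4class{PairedIntensityTable}s with uncorrected after-values.
#' @export
simulatePairedIntensities <- function(azMap,
                                      mode = c("null", "additive",
                                               "multiplicative"),
                                      param = 0, noiseCV = 0.05,
                                      vehicleDrift = 1,
                                      nVehicleAZ = nrow(azTable(azMap)),
                                      seed = 1) {
    mode <- match.arg(mode)
    stopifnot(noiseCV >= 0, vehicleDrift > 0)
    if (mode == "multiplicative" && param <= 0)
        stop("multiplicative factor must be > 0")
    set.seed(seed)
    before <- azTable(azMap)$true_level
    transformed <- switch(mode,
        null = before,
        additive = before + param,
        multiplicative = param * before)
    afterT <- transformed * (1 + rnorm(length(before), 0, noiseCV)) *
        vehicleDrift
    vehicleBefore <- rgamma(nVehicleAZ,
        shape = azMap@params$levelShape %||% 2,
        scale = azMap@params$levelScale %||% 1)
    afterV <- vehicleBefore * (1 + rnorm(nVehicleAZ, 0, noiseCV)) *
        vehicleDrift
    mk <- function(id, b, a, group) {
        new("PairedIntensityTable",
            table = data.frame(punctum_id = id, baseline = b, after_raw = a,
                               after_corrected = a, delta = a - b),
            correctionFactor = NA_real_, group = group)
    }
    list(treated = mk(azTable(azMap)$az_id, before, afterT, "treated"),
         vehicle = mk(seq_len(nVehicleAZ), vehicleBefore, afterV, "vehicle"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a ratiometric calcium-transient recording
#'
#' Builds a two-channel recording: 1 s of rest, \code{nSweeps} single action
#' potentials at 1 Hz (each an instantaneous rise of \code{deltaR} decaying
#' exponentially with time constant \code{tau}), a 20 Hz style train modeled
#' as a saturating plateau of amplitude \code{plateauDR}, and a tail. The
#' calcium-insensitive channel is constant, so the ground-truth ratio is
#' known exactly; Gaussian noise of SD \code{noiseSD} (ratio units) is added
#' to the calcium-sensitive channel. Stimulus times fall exactly on the
#' sample grid.
#'
#' @param restingR resting ratio level (> 0).
#' @param deltaR single-AP peak amplitude (ratio units).
#' @param tau decay time constant (s).
#' @param nSweeps number of single-AP sweeps at 1 Hz.
#' @param trainRate,trainDuration train stimulation rate (Hz) and duration
#'   (s); \code{trainRate = 0} omits the train.
#' @param plateauDR train plateau amplitude above rest.
#' @param trainTauRise rise time constant of the train plateau (s).
#' @param noiseSD Gaussian noise SD on the ratio.
#' @param sampleRate samples per second.
#' @param af647Level constant level of the insensitive channel.
#' @param seed integer seed.
#' @return a \linkS4class{TransientRecording}; ground truth is kept in
#'   \code{@params}.
#' @export
simulateTransientRecording <- function(restingR = 2.74, deltaR = 4.5,
                                       tau = 0.08, nSweeps = 10,
                                       trainRate = 20, trainDuration = 1,
                                       plateauDR = 9.71,
                                       trainTauRise = 0.08,
                                       noiseSD = 0, sampleRate = 114,
                                       af647Level = 100, seed = 1) {
    stopifnot(restingR > 0, tau > 0, nSweeps >= 1, sampleRate > 0)
    set.seed(seed)
    stimTimes <- seq_len(nSweeps)            # 1 Hz from t = 1 s
    trainStart <- nSweeps + 2
    tEnd <- if (trainRate > 0) trainStart + trainDuration + 1.5 else
        nSweeps + 2
    time <- seq(0, tEnd, by = 1 / sampleRate)
    ## snap stimulus times onto the sample grid
    stimTimes <- round(stimTimes * sampleRate) / sampleRate
    R <- rep(restingR, length(time))
    for (ts in stimTimes) {
        on <- time >= ts - 1e-12
        R[on] <- R[on] + deltaR * exp(-(time[on] - ts) / tau)
    }
    train <- list()
    if (trainRate > 0) {
        t0 <- round(trainStart * sampleRate) / sampleRate
        t1 <- t0 + trainDuration
        inTrain <- time >= t0 & time <= t1
        R[inTrain] <- R[inTrain] +
            plateauDR * (1 - exp(-(time[inTrain] - t0) / trainTauRise))
        after <- time > t1
        endLevel <- plateauDR * (1 - exp(-trainDuration / trainTauRise))
        R[after] <- R[after] + endLevel * exp(-(time[after] - t1) / tau)
        train <- list(start = t0, rate = trainRate,
                      duration = trainDuration)
    }
    if (noiseSD > 0) R <- R + rnorm(length(R), 0, noiseSD)
    new("TransientRecording", time = time, rhod = R * af647Level,
        af647 = rep(af647Level, length(time)), stimulusTimes = stimTimes,
        train = train,
        params = list(restingR = restingR, deltaR = deltaR, tau = tau,
                      plateauDR = plateauDR, noiseSD = noiseSD,
                      seed = seed))
}

#' Simulate an intracellular recording for quantal analysis
#'
#' Miniature EJP amplitudes are drawn from a gamma distribution with the
#' stated mean and coefficient of variation (a positive, right-skewed
#' amplitude model). Evoked EJP amplitudes are sums of a Poisson number of
#' quanta (mean \code{quantalContent}) of sizes drawn from the same
#' miniature distribution.
#'
#' @param mejpMean mean miniature amplitude (mV).
#' @param mejpCV coefficient of variation of miniature amplitudes; 0 makes
#'   all amplitudes equal to the mean.
#' @param nMEJPs number of miniature events (>= 1).
#' @param quantalContent expected quanta per evoked response.
#' @param nEJPs number of evoked responses.
#' @param vRest resting potential (mV).
#' @param rIn input resistance (MOhm).
#' @param label recording label.
#' @param seed integer seed.
#' @return an \linkS4class{EphysRecording}.
#' @export
simulateEphysRecording <- function(mejpMean = 0.9, mejpCV = 0.3,
                                   nMEJPs = 120, quantalContent = 30,
                                   nEJPs = 25, vRest = -70, rIn = 10,
                                   label = "rec", seed = 1) {
    if (nMEJPs < 1) stop("nMEJPs must be >= 1")
    stopifnot(mejpMean > 0, mejpCV >= 0, nEJPs >= 1, quantalContent > 0)
    set.seed(seed)
    drawAmp <- function(n) {
        if (mejpCV == 0) rep(mejpMean, n)
        else rgamma(n, shape = 1 / mejpCV^2, scale = mejpMean * mejpCV^2)
    }
    mejp <- drawAmp(nMEJPs)
    nq <- pmax(rpois(nEJPs, quantalContent), 1L)
    ejp <- vapply(nq, function(k) sum(drawAmp(k)), numeric(1))
    new("EphysRecording", mejpAmplitudes = mejp, ejpAmplitudes = ejp,
        vRest = vRest, rIn = rIn, label = label)
}
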