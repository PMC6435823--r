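## Optical quantal analysis: stimulus-locked event detection in movies,
## nearest-neighbour assignment of events to puncta, per-AZ release
## probability and its correlation with channel intensity.

#' Detect stimulus-locked events in a movie
#'
#' The baseline image (mean of the designated non-stimulus frames) is
#' subtracted from every frame. In each stimulus frame, above-threshold
#' local maxima are candidate events; a candidate is kept only if a local
#' peak persists at its location (within \code{matchRadius} pixels) for at
#' least \code{persistence} subsequent frames with non-increasing amplitude.
#' Event coordinates are the thresholded-maximum pixel (no sub-pixel fit).
#'
#' @param movie an \linkS4class{AZMovie}.
#' @param threshold event amplitude threshold on the baseline-subtracted
#'   image (a.u.).
#' @param baselineFrames indices of baseline frames; defaults to the
#'   movie's own.
#' @param persistence required number of persisting subsequent frames
#'   (>= 1).
#' @param matchRadius search radius (px) for the persisting peak.
#' @param noiseTolerance prominence tolerance for the in-frame maxima.
#' @param persistenceFloor fraction of \code{threshold} the persisting peak
#'   must still exceed.
#' @param amplitudeSlack tolerated amplitude increase between consecutive
#'   frames, as a fraction of the initial amplitude (allows noise on top of
#'   a decaying flash).
#' @return an \linkS4class{EventStream} with 0-based stimulus indices.
#' @export
detectEvents <- function(movie, threshold,
                         baselineFrames = movie@baselineFrames,
                         persistence = 2, matchRadius = 2,
                         noiseTolerance = 0, persistenceFloor = 0.2,
                         amplitudeSlack = 0.1) {
    stopifnot(persistence >= 1, length(baselineFrames) >= 1)
    nFrames <- length(movie@frames)
    if (any(movie@stimFrames > nFrames))
        stop("stimulus frames beyond movie length")
    if (any(baselineFrames %in% movie@stimFrames))
        stop("baseline frames must be disjoint from stimulus frames")
    base <- Reduce(`+`, movie@frames[baselineFrames]) /
        length(baselineFrames)
    H <- nrow(base); W <- ncol(base)
    evs <- list()
    for (s in seq_along(movie@stimFrames)) {
        f0 <- movie@stimFrames[s]
        sub0 <- movie@frames[[f0]] - base
        mx <- findMaxima(sub0, noiseTolerance, threshold)
        if (!nrow(mx)) next
        keep <- logical(nrow(mx))
        for (i in seq_len(nrow(mx))) {
            r <- mx$y[i] + 1L; c <- mx$x[i] + 1L
            prev <- mx$value[i]
            ok <- TRUE
            for (k in seq_len(persistence)) {
                f <- f0 + k
                if (f > nFrames) { ok <- FALSE; break }
                rows <- max(1, r - matchRadius):min(H, r + matchRadius)
                cols <- max(1, c - matchRadius):min(W, c + matchRadius)
                m <- max(movie@frames[[f]][rows, cols] - base[rows, cols])
                if (m < persistenceFloor * threshold ||
                    m > prev + amplitudeSlack * mx$value[i]) {
                    ok <- FALSE
                    break
                }
                prev <- m
            }
            keep[i] <- ok
        }
        if (any(keep))
            evs[[length(evs) + 1L]] <- data.frame(
                stimulus = s - 1L, x = mx$x[keep], y = mx$y[keep])
    }
    ev <- if (length(evs)) do.call(rbind, evs) else
        data.frame(stimulus = integer(0), x = numeric(0), y = numeric(0))
    new("EventStream", events = ev,
        nStimuli = length(movie@stimFrames))
}

#' Assign events to puncta by nearest-neighbour Euclidean distance
#'
#' Each event maps to the punctum whose centroid is closest in Euclidean
#' distance. Ties go to the lowest punctum_id. If \code{maxRadius} is
#' finite and the minimal distance exceeds it the event is flagged
#' unassigned (punctum_id NA).
#'
#' @param events an \linkS4class{EventStream} or a data.frame with columns
#'   \code{stimulus}, \code{x}, \code{y}.
#' @param puncta a \linkS4class{PunctaTable} (nonempty).
#' @param maxRadius maximum assignment distance in px; \code{Inf} (default)
#'   for pure nearest neighbour.
#' @return data.frame: \code{stimulus}, \code{x}, \code{y},
#'   \code{punctum_id} (NA when unassigned), \code{distance}.
#' @export
assignEvents <- function(events, puncta, maxRadius = Inf) {
    ev <- if (is(events, "EventStream")) events@events else events
    pt <- azTable(puncta)
    if (!nrow(pt)) stop("puncta table is empty")
    out <- data.frame(stimulus = ev$stimulus, x = ev$x, y = ev$y,
                      punctum_id = rep(NA_integer_, nrow(ev)),
                      distance = rep(NA_real_, nrow(ev)))
    if (!nrow(ev)) return(out)
    ## order puncta by id so which.min's first-match rule breaks ties
    ## toward the lowest punctum_id
    o <- order(pt$punctum_id)
    px <- pt$x[o]; py <- pt$y[o]; pid <- pt$punctum_id[o]
    d2 <- outer(ev$x, px, `-`)^2 + outer(ev$y, py, `-`)^2
    j <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(d2[cbind(seq_len(nrow(ev)), j)])
    assigned <- dmin <= maxRadius
    out$punctum_id[assigned] <- pid[j[assigned]]
    out$distance <- dmin
    out
}

#' Estimate per-punctum release probability
#'
#' Pr is per-stimulus binary: multiple assigned events at one punctum in one
#' stimulus collapse to a single release. The estimate is the number of
#' distinct stimuli with at least one event divided by the number of
#' stimuli.
#'
#' @param assignments data.frame from \code{\link{assignEvents}}.
#' @param nStimuli number of stimuli delivered (from the stimulus log).
#' @param puncta optional \linkS4class{PunctaTable}; when given, the output
#'   has a row for every punctum (zero counts included), which is required
#'   for intensity correlation.
#' @return a \linkS4class{ReleaseTable}.
#' @export
estimatePr <- function(assignments, nStimuli, puncta = NULL) {
    stopifnot(nStimuli >= 1)
    ok <- !is.na(assignments$punctum_id)
    uniq <- unique(assignments[ok, c("punctum_id", "stimulus")])
    counts <- table(factor(uniq$punctum_id))
    ids <- if (!is.null(puncta)) sort(azTable(puncta)$punctum_id) else
        sort(as.integer(names(counts)))
    cnt <- as.integer(counts[as.character(ids)])
    cnt[is.na(cnt)] <- 0L
    new("ReleaseTable",
        table = data.frame(punctum_id = ids, event_count = cnt,
                           n_stimuli = as.integer(nStimuli),
                           pr_estimate = cnt / nStimuli),
        nStimuli = as.integer(nStimuli),
        unassigned = sum(!ok))
}

#' Correlate punctum intensity with release probability
#'
#' Per-NMJ Pearson correlation between summed punctum intensity and
#' estimated release probability, and the unweighted average r across NMJs.
#' An NMJ with fewer than 3 AZs or zero variance in either variable is
#' reported as excluded and omitted from the average.
#'
#' @param puncta a \linkS4class{PunctaTable} or list of them (one per NMJ).
#' @param release a \linkS4class{ReleaseTable} or list matching
#'   \code{puncta}.
#' @param nmjNames optional NMJ labels.
#' @return a \linkS4class{CorrelationResult}.
#' @export
correlateIntensityPr <- function(puncta, release, nmjNames = NULL) {
    if (is(puncta, "PunctaTable")) puncta <- list(puncta)
    if (is(release, "ReleaseTable")) release <- list(release)
    stopifnot(length(puncta) == length(release))
    if (is.null(nmjNames)) nmjNames <- paste0("NMJ", seq_along(puncta))
    rows <- lapply(seq_along(puncta), function(i) {
        pt <- azTable(puncta[[i]])
        rl <- azTable(release[[i]])
        m <- merge(pt[, c("punctum_id", "sum_intensity")],
                   rl[, c("punctum_id", "pr_estimate")], by = "punctum_id")
        bad <- nrow(m) < 3 || sd(m$sum_intensity) == 0 ||
            sd(m$pr_estimate) == 0
        data.frame(nmj = nmjNames[i],
                   r = if (bad) NA_real_ else
                       cor(m$sum_intensity, m$pr_estimate),
                   n = nrow(m), excluded = bad)
    })
    perNMJ <- do.call(rbind, rows)
    if (all(perNMJ$excluded))
        warning("no NMJ had computable intensity-Pr correlation")
    new("CorrelationResult", perNMJ = perNMJ,
        averageR = mean(perNMJ$r[!perNMJ$excluded]))
}
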