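## Ratiometric presynaptic calcium-transient analysis: ratio traces, sweep
## averaging, peak amplitude and decay time constant, train plateau, and
## MAD-based preparation exclusion.

#' Compute the ratio trace of a recording
#'
#' Elementwise ratio of the calcium-sensitive to the calcium-insensitive
#' channel; invariant to any common scaling of both channels.
#'
#' @param recording a \linkS4class{TransientRecording}.
#' @return data.frame with columns \code{time} and \code{R}.
#' @export
ratioTrace <- function(recording) {
    if (any(recording@af647 <= 0))
        stop("insensitive-channel values must be positive")
    data.frame(time = recording@time,
               R = recording@rhod / recording@af647)
}

#' Average stimulus-aligned single-AP sweeps
#'
#' Extracts a window around every single-AP stimulus and averages the
#' sweeps pointwise. Sweeps whose window overlaps the stimulus train are
#' excluded with a warning; iid noise is reduced by 1/sqrt(number of
#' sweeps).
#'
#' @param trace data.frame with \code{time} and \code{R} (from
#'   \code{\link{ratioTrace}}).
#' @param stimulusTimes single-AP stimulus times (s), >= 1.
#' @param window c(before, after) in seconds around each stimulus.
#' @param train optional list(start, duration) of the train to avoid.
#' @return data.frame with \code{time} (relative to the stimulus) and
#'   \code{R}; attribute \code{nSweeps} gives the sweeps averaged.
#' @export
averageSingleAPSweeps <- function(trace, stimulusTimes,
                                  window = c(-0.2, 0.6), train = NULL) {
    if (!length(stimulusTimes)) stop("no stimulus times given")
    dt <- median(diff(trace$time))
    iRel <- seq(round(window[1] / dt), round(window[2] / dt))
    keep <- logical(length(stimulusTimes))
    sweeps <- list()
    for (i in seq_along(stimulusTimes)) {
        ts <- stimulusTimes[i]
        i0 <- which.min(abs(trace$time - ts))
        idx <- i0 + iRel
        if (min(idx) < 1 || max(idx) > nrow(trace))
            stop("sweep window outside recording for stimulus at ", ts)
        if (!is.null(train) && length(train) &&
            ts + window[2] > train$start &&
            ts + window[1] < train$start + train$duration) {
            keep[i] <- FALSE
            next
        }
        keep[i] <- TRUE
        sweeps[[length(sweeps) + 1L]] <- trace$R[idx]
    }
    if (!all(keep))
        warning(sum(!keep), " sweep(s) overlapping the train excluded")
    if (!length(sweeps)) stop("no usable sweeps")
    avg <- Reduce(`+`, sweeps) / length(sweeps)
    out <- data.frame(time = iRel * dt, R = avg)
    attr(out, "nSweeps") <- length(sweeps)
    out
}

#' Peak amplitude and decay time constant of an averaged transient
#'
#' The peak amplitude is the trace maximum (after the stimulus) minus the
#' mean over the baseline window. The decay time constant comes from a
#' nonlinear least-squares fit of A exp(-t / tau) + B from the peak onward,
#' initialized at the observed time-to-1/e; the offset B absorbs a baseline
#' not reached within the window.
#'
#' @param trace averaged data.frame with \code{time} (stimulus at 0) and
#'   \code{R}.
#' @param baselineWindow c(t0, t1) in seconds, before the stimulus.
#' @return list with \code{restingR}, \code{deltaR}, \code{tau},
#'   \code{converged}.
#' @export
peakAndTau <- function(trace, baselineWindow = c(-0.2, -0.01)) {
    bl <- trace$R[trace$time >= baselineWindow[1] &
                  trace$time <= baselineWindow[2]]
    if (!length(bl)) stop("baseline window contains no samples")
    resting <- mean(bl)
    post <- trace[trace$time >= 0, ]
    ipk <- which.max(post$R)
    deltaR <- post$R[ipk] - resting
    if (deltaR <= 0) stop("no positive transient after the stimulus")
    dec <- post[ipk:nrow(post), ]
    t <- dec$time - dec$time[1]
    y <- dec$R
    ## time-to-1/e initialization
    target <- resting + deltaR / exp(1)
    below <- which(y <= target)
    tau0 <- if (length(below)) max(t[below[1]], 2 * (t[2] - t[1]))
            else max(t) / 2
    fit <- tryCatch(
        minpack.lm::nlsLM(y ~ A * exp(-t / tau) + B,
                          start = list(A = deltaR, tau = tau0, B = resting),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    if (is.null(fit)) stop("decay fit did not converge")
    tau <- unname(coef(fit)["tau"])
    if (tau <= 0) stop("decay fit produced nonpositive tau")
    list(restingR = resting, deltaR = deltaR, tau = tau, converged = TRUE)
}

#' Train plateau amplitude
#'
#' Mean ratio over the final fraction (default last half) of the train
#' window, minus the baseline level.
#'
#' @param trace data.frame with \code{time} and \code{R}.
#' @param trainWindow c(start, end) of the train (s).
#' @param baseline baseline ratio level to subtract.
#' @param finalFraction fraction of the window, from the end, to average.
#' @return plateau amplitude (ratio units).
#' @export
trainPlateau <- function(trace, trainWindow, baseline,
                         finalFraction = 0.5) {
    stopifnot(finalFraction > 0, finalFraction <= 1)
    if (trainWindow[1] < min(trace$time) - 1e-9 ||
        trainWindow[2] > max(trace$time) + 1e-9)
        stop("train window outside recording")
    t0 <- trainWindow[2] - finalFraction * diff(trainWindow)
    sel <- trace$time >= t0 & trace$time <= trainWindow[2]
    mean(trace$R[sel]) - baseline
}

#' Median-absolute-deviation outlier filter
#'
#' Keeps values within k times the raw (unscaled) MAD of the median,
#' bounds inclusive: MAD = median(|x - median(x)|), with no 1.4826
#' consistency factor (set \code{scaled = TRUE} for the consistent
#' variant). When the MAD is zero only values equal to the median are
#' kept, with a warning. The keep mask is invariant under affine
#' rescaling of the values.
#'
#' @param values numeric vector (>= 3 values).
#' @param k multiplier of the MAD (default 3).
#' @param scaled apply the 1.4826 normal-consistency factor.
#' @return list with \code{keep} (logical mask), \code{lower},
#'   \code{upper}, \code{median}, \code{mad}.
#' @export
madOutlierFilter <- function(values, k = 3, scaled = FALSE) {
    if (length(values) < 3) stop("need >= 3 values")
    med <- median(values)
    m <- mad(values, constant = if (scaled) 1.4826 else 1)
    if (m == 0) {
        warning("MAD is zero; keeping only values equal to the median")
        return(list(keep = values == med, lower = med, upper = med,
                    median = med, mad = 0))
    }
    lower <- med - k * m
    upper <- med + k * m
    list(keep = values >= lower & values <= upper, lower = lower,
         upper = upper, median = med, mad = m)
}

#' Quality gate for a transient summary
#'
#' Passes only when the decay fit converged and tau is strictly below the
#' limit (default 0.250 s).
#'
#' @param summary list with \code{tau} and \code{converged} (as from
#'   \code{\link{peakAndTau}}), or a numeric tau.
#' @param tauLimit gate (s); strict inequality.
#' @return logical.
#' @export
qcTransient <- function(summary, tauLimit = 0.250) {
    if (is.numeric(summary)) summary <- list(tau = summary,
                                             converged = TRUE)
    isTRUE(summary$converged) && summary$tau < tauLimit
}

#' Summarize a transient recording
#'
#' Convenience chain: ratio trace, single-AP sweep averaging, peak and tau,
#' train plateau (when a train is present), and the tau quality gate.
#'
#' @param recording a \linkS4class{TransientRecording}.
#' @param window,baselineWindow see \code{\link{averageSingleAPSweeps}} and
#'   \code{\link{peakAndTau}}.
#' @return one-row data.frame: restingR, deltaR, tau, trainDeltaR, qcPass.
#' @export
summarizeTransient <- function(recording, window = c(-0.2, 0.6),
                               baselineWindow = c(-0.2, -0.01)) {
    tr <- ratioTrace(recording)
    avg <- averageSingleAPSweeps(tr, recording@stimulusTimes,
                                 window = window, train = recording@train)
    pk <- peakAndTau(avg, baselineWindow)
    trainDR <- NA_real_
    if (length(recording@train))
        trainDR <- trainPlateau(tr,
            c(recording@train$start,
              recording@train$start + recording@train$duration),
            baseline = pk$restingR)
    data.frame(restingR = pk$restingR, deltaR = pk$deltaR, tau = pk$tau,
               trainDeltaR = trainDR, qcPass = qcTransient(pk))
}
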