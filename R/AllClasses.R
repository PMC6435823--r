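#' @import methods
#' @importFrom stats median rnorm rgamma rbinom runif rpois sd mad cor lm coef
#'   fisher.test t.test wilcox.test shapiro.test var.test pnorm pchisq qbeta
#'   complete.cases setNames
#' @importFrom utils write.csv read.csv
#' @useDynLib azquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom sandwich vcovHC
NULL

## Coordinate convention used throughout: (x, y), 0-based, continuous, with
## pixel centers at integer coordinates. A matrix element [r, c] corresponds
## to (x = c - 1, y = r - 1).

#' Ground-truth active-zone map
#'
#' Container for a simulated field of active zones (AZs): planted centers,
#' true channel levels for two correlated channels, and true per-AZ release
#' probability. This is the latent truth that every downstream stage of the
#' pipeline tries to recover.
#'
#' @slot table data.frame with columns \code{az_id}, \code{x}, \code{y},
#'   \code{true_level}, \code{second_level}, \code{true_pr}.
#' @slot fieldWidth,fieldHeight field size in pixels.
#' @slot pixelSize physical pixel size in micrometres.
#' @slot minSpacing minimum pairwise center distance in pixels.
#' @slot params list of generator parameters (including the seed).
#' @exportClass AZMap
setClass("AZMap",
    representation(table = "data.frame", fieldWidth = "numeric",
                   fieldHeight = "numeric", pixelSize = "numeric",
                   minSpacing = "numeric", params = "list"))

setValidity("AZMap", function(object) {
    tb <- object@table
    need <- c("az_id", "x", "y", "true_level", "second_level", "true_pr")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns", paste(need, collapse = ", ")))
    if (any(tb$true_pr < 0 | tb$true_pr > 1)) return("true_pr outside [0, 1]")
    if (any(tb$true_level <= 0)) return("true_level must be > 0")
    if (nrow(tb) > 1) {
        d <- as.matrix(stats::dist(tb[, c("x", "y")]))
        diag(d) <- Inf
        if (min(d) < object@minSpacing - 1e-9)
            return("pairwise center distance below minSpacing")
    }
    TRUE
})

#' Single-channel image frame
#'
#' @slot pixels numeric matrix of nonnegative intensities; element [r, c] is
#'   the pixel at 0-based coordinate (x = c - 1, y = r - 1).
#' @slot pixelSize micrometres per pixel.
#' @slot channel channel label.
#' @exportClass ImageFrame
setClass("ImageFrame",
    representation(pixels = "matrix", pixelSize = "numeric",
                   channel = "character"))

setValidity("ImageFrame", function(object) {
    if (!all(is.finite(object@pixels))) return("pixels must be finite")
    TRUE
})

#' Stimulus-locked movie
#'
#' @slot frames list of numeric matrices, one per frame, identical shape.
#' @slot frameRate frames per second.
#' @slot stimFrames 1-based indices of stimulus-locked frames, strictly
#'   increasing.
#' @slot baselineFrames 1-based indices of non-stimulus baseline frames.
#' @slot pixelSize micrometres per pixel.
#' @exportClass AZMovie
setClass("AZMovie",
    representation(frames = "list", frameRate = "numeric",
                   stimFrames = "integer", baselineFrames = "integer",
                   pixelSize = "numeric"))

setValidity("AZMovie", function(object) {
    if (object@frameRate <= 0) return("frameRate must be > 0")
    n <- length(object@frames)
    if (length(object@stimFrames) &&
        (is.unsorted(object@stimFrames, strictly = TRUE) ||
         any(object@stimFrames < 1) || any(object@stimFrames > n)))
        return("stimFrames must be strictly increasing and within range")
    TRUE
})

#' Table of detected puncta
#'
#' One row per detected punctum: centroid, area, mean and summed intensity.
#' The sum is the product of mean intensity and pixel area, the per-AZ
#' abundance proxy used throughout.
#'
#' @slot table data.frame with columns \code{punctum_id}, \code{x}, \code{y},
#'   \code{area}, \code{mean_intensity}, \code{sum_intensity}.
#' @slot channel source channel label.
#' @slot params detection parameters used (provenance).
#' @exportClass PunctaTable
setClass("PunctaTable",
    representation(table = "data.frame", channel = "character",
                   params = "list"))

setValidity("PunctaTable", function(object) {
    tb <- object@table
    need <- c("punctum_id", "x", "y", "area", "mean_intensity",
              "sum_intensity")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(tb$punctum_id)) return("punctum_ids must be unique")
    if (nrow(tb) && any(tb$area < 1)) return("area must be >= 1")
    if (nrow(tb) &&
        any(abs(tb$sum_intensity - tb$mean_intensity * tb$area) >
            1e-6 * pmax(1, abs(tb$sum_intensity))))
        return("sum_intensity must equal mean_intensity * area")
    TRUE
})

#' Stream of stimulus-indexed events
#'
#' @slot events data.frame with columns \code{stimulus} (0-based index),
#'   \code{x}, \code{y}.
#' @slot nStimuli total number of stimuli delivered.
#' @exportClass EventStream
setClass("EventStream",
    representation(events = "data.frame", nStimuli = "integer"))

setValidity("EventStream", function(object) {
    ev <- object@events
    if (!all(c("stimulus", "x", "y") %in% names(ev)))
        return("events must have columns stimulus, x, y")
    if (nrow(ev) && (any(ev$stimulus < 0) ||
                     any(ev$stimulus >= object@nStimuli)))
        return("stimulus indices must lie in [0, nStimuli)")
    TRUE
})

#' Per-punctum release table
#'
#' @slot table data.frame with columns \code{punctum_id}, \code{event_count},
#'   \code{n_stimuli}, \code{pr_estimate}.
#' @slot nStimuli number of stimuli.
#' @slot unassigned number of detected events not assigned to any punctum.
#' @exportClass ReleaseTable
setClass("ReleaseTable",
    representation(table = "data.frame", nStimuli = "integer",
                   unassigned = "integer"))

setValidity("ReleaseTable", function(object) {
    tb <- object@table
    if (nrow(tb) && (any(tb$pr_estimate < 0) || any(tb$pr_estimate > 1)))
        return("pr_estimate outside [0, 1]")
    TRUE
})

#' Paired before/after intensity table
#'
#' @slot table data.frame with columns \code{punctum_id}, \code{baseline},
#'   \code{after_raw}, \code{after_corrected}, \code{delta}
#'   (= after_corrected - baseline).
#' @slot correctionFactor vehicle correction factor applied
#'   (NA before correction).
#' @slot group group label ("treated", "vehicle", ...).
#' @exportClass PairedIntensityTable
setClass("PairedIntensityTable",
    representation(table = "data.frame", correctionFactor = "numeric",
                   group = "character"))

setValidity("PairedIntensityTable", function(object) {
    tb <- object@table
    need <- c("punctum_id", "baseline", "after_raw", "after_corrected",
              "delta")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns", paste(need, collapse = ", ")))
    TRUE
})

#' Additive-versus-multiplicative scaling fit
#'
#' Result of discriminating additive (y = x + c) from multiplicative
#' (y = m x) scaling of paired per-AZ intensities, plus the unconstrained
#' least-squares line for reference.
#'
#' @slot freeSlope,freeIntercept,rSquared unconstrained OLS fit of after on
#'   baseline.
#' @slot freeSlopeCI 95 percent confidence interval for the free slope with
#'   heteroscedasticity-robust (HC3) standard errors, appropriate under the
#'   multiplicative measurement-noise model.
#' @slot additiveC offset of the one-parameter additive model, with
#'   \code{rssAdd} its residual sum of squares and \code{aicAdd} its AIC.
#' @slot multiplicativeM factor of the one-parameter multiplicative model,
#'   with \code{rssMult} and \code{aicMult}.
#' @slot selected "additive", "multiplicative" or "indistinguishable".
#' @slot relTol relative RSS tolerance used for the indistinguishable call.
#' @slot n number of puncta fitted.
#' @exportClass ScalingFit
setClass("ScalingFit",
    representation(freeSlope = "numeric", freeIntercept = "numeric",
                   rSquared = "numeric", freeSlopeCI = "numeric",
                   additiveC = "numeric",
                   rssAdd = "numeric", multiplicativeM = "numeric",
                   rssMult = "numeric", aicAdd = "numeric",
                   aicMult = "numeric", selected = "character",
                   relTol = "numeric", n = "integer"))

#' Tercile change-frequency report
#'
#' @slot table data.frame with one row per baseline tercile: \code{tercile},
#'   \code{n}, \code{n_nochange} (delta <= 0), \code{prop_nochange}.
#' @slot fisher data.frame of pairwise two-sided Fisher exact tests.
#' @slot n total punctum count.
#' @exportClass TercileReport
setClass("TercileReport",
    representation(table = "data.frame", fisher = "data.frame",
                   n = "integer"))

#' Intensity-release correlation result
#'
#' @slot perNMJ data.frame with one row per NMJ: \code{nmj}, \code{r},
#'   \code{n}, \code{excluded} (TRUE when r could not be computed).
#' @slot averageR unweighted mean r over non-excluded NMJs.
#' @exportClass CorrelationResult
setClass("CorrelationResult",
    representation(perNMJ = "data.frame", averageR = "numeric"))

#' Ratiometric calcium-transient recording
#'
#' Two fluorescence channels sampled on a common time base: a calcium
#' sensitive dye (rhod) and a calcium-insensitive volume marker (AF647).
#' The analyte is their ratio R = rhod / AF647.
#'
#' @slot time sample times in seconds, strictly increasing.
#' @slot rhod,af647 fluorescence series, same length as time; af647 > 0.
#' @slot stimulusTimes single action-potential stimulus times (s).
#' @slot train list(start, rate, duration) describing the stimulus train,
#'   or empty list if none.
#' @slot params generator parameters (ground truth) when simulated.
#' @exportClass TransientRecording
setClass("TransientRecording",
    representation(time = "numeric", rhod = "numeric", af647 = "numeric",
                   stimulusTimes = "numeric", train = "list",
                   params = "list"))

setValidity("TransientRecording", function(object) {
    n <- length(object@time)
    if (length(object@rhod) != n || length(object@af647) != n)
        return("time, rhod and af647 must have equal length")
    if (n > 1 && is.unsorted(object@time, strictly = TRUE))
        return("time must be strictly increasing")
    if (any(object@af647 <= 0)) return("af647 must be positive everywhere")
    TRUE
})

#' Intracellular recording for quantal analysis
#'
#' @slot mejpAmplitudes miniature EJP amplitudes (mV).
#' @slot ejpAmplitudes evoked EJP amplitudes (mV).
#' @slot vRest resting membrane potential (mV).
#' @slot rIn input resistance (MOhm).
#' @slot label recording label.
#' @exportClass EphysRecording
setClass("EphysRecording",
    representation(mejpAmplitudes = "numeric", ejpAmplitudes = "numeric",
                   vRest = "numeric", rIn = "numeric", label = "character"))

setValidity("EphysRecording", function(object) {
    if (length(object@mejpAmplitudes) && any(object@mejpAmplitudes <= 0))
        return("mEJP amplitudes must be positive")
    if (length(object@ejpAmplitudes) && any(object@ejpAmplitudes <= 0))
        return("EJP amplitudes must be positive")
    TRUE
})
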