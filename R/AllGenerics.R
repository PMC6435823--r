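#' Extract the underlying data.frame of a container
#'
#' Accessor for the tabular payload of the package's S4 containers
#' (\linkS4class{AZMap}, \linkS4class{PunctaTable},
#' \linkS4class{ReleaseTable}, \linkS4class{PairedIntensityTable},
#' \linkS4class{EventStream}, \linkS4class{TercileReport}).
#'
#' @param x an azquant container object.
#' @return a data.frame.
#' @export
setGeneric("azTable", function(x) standardGeneric("azTable"))

#' @rdname azTable
#' @export
setMethod("azTable", "AZMap", function(x) x@table)
#' @rdname azTable
#' @export
setMethod("azTable", "PunctaTable", function(x) x@table)
#' @rdname azTable
#' @export
setMethod("azTable", "ReleaseTable", function(x) x@table)
#' @rdname azTable
#' @export
setMethod("azTable", "PairedIntensityTable", function(x) x@table)
#' @rdname azTable
#' @export
setMethod("azTable", "EventStream", function(x) x@events)
#' @rdname azTable
#' @export
setMethod("azTable", "TercileReport", function(x) x@table)

#' Pixel matrix of an image frame
#' @param x an \linkS4class{ImageFrame}.
#' @return numeric matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname pixels
#' @export
setMethod("pixels", "ImageFrame", function(x) x@pixels)

#' Number of stimuli underlying a stream or release table
#' @param x an \linkS4class{EventStream} or \linkS4class{ReleaseTable}.
#' @return integer count.
#' @export
setGeneric("nStimuli", function(x) standardGeneric("nStimuli"))
#' @rdname nStimuli
#' @export
setMethod("nStimuli", "EventStream", function(x) x@nStimuli)
#' @rdname nStimuli
#' @export
setMethod("nStimuli", "ReleaseTable", function(x) x@nStimuli)

#' Model selected by a scaling fit
#' @param x a \linkS4class{ScalingFit}.
#' @return character: "additive", "multiplicative" or "indistinguishable".
#' @export
setGeneric("selectedModel", function(x) standardGeneric("selectedModel"))
#' @rdname selectedModel
#' @export
setMethod("selectedModel", "ScalingFit", function(x) x@selected)

setMethod("show", "AZMap", function(object) {
    cat("AZMap with", nrow(object@table), "active zones on a",
        object@fieldWidth, "x", object@fieldHeight, "px field\n")
    cat("  true_level: median", signif(median(object@table$true_level), 3),
        " true_pr: median", signif(median(object@table$true_pr), 3), "\n")
})

setMethod("show", "ImageFrame", function(object) {
    cat("ImageFrame", paste0("[", nrow(object@pixels), " x ",
        ncol(object@pixels), "]"), "channel:", object@channel,
        " pixel:", object@pixelSize, "um\n")
})

setMethod("show", "AZMovie", function(object) {
    cat("AZMovie:", length(object@frames), "frames at", object@frameRate,
        "fps;", length(object@stimFrames), "stimulus frames,",
        length(object@baselineFrames), "baseline frames\n")
})

setMethod("show", "PunctaTable", function(object) {
    cat("PunctaTable:", nrow(object@table), "puncta (channel:",
        object@channel, ")\n")
})

setMethod("show", "EventStream", function(object) {
    cat("EventStream:", nrow(object@events), "events over",
        object@nStimuli, "stimuli\n")
})

setMethod("show", "ReleaseTable", function(object) {
    tb <- object@table
    cat("ReleaseTable:", nrow(tb), "puncta over", object@nStimuli,
        "stimuli;", object@unassigned, "unassigned events\n")
    if (nrow(tb))
        cat("  Pr estimate: median", signif(median(tb$pr_estimate), 3), "\n")
})

setMethod("show", "PairedIntensityTable", function(object) {
    cat("PairedIntensityTable (", object@group, "):", nrow(object@table),
        "puncta; vehicle correction factor:",
        ifelse(is.na(object@correctionFactor), "not applied",
               signif(object@correctionFactor, 4)), "\n")
})

setMethod("show", "ScalingFit", function(object) {
    cat("ScalingFit on", object@n, "paired puncta\n")
    cat(sprintf("  free fit: slope %.3f, intercept %.3f, R^2 %.3f\n",
                object@freeSlope, object@freeIntercept, object@rSquared))
    cat(sprintf("  additive c = %.3f (RSS %.4g) | multiplicative m = %.3f (RSS %.4g)\n",
                object@additiveC, object@rssAdd, object@multiplicativeM,
                object@rssMult))
    cat("  selected:", object@selected, "\n")
})

setMethod("show", "TercileReport", function(object) {
    cat("TercileReport over", object@n, "puncta\n")
    print(object@table, row.names = FALSE)
})

setMethod("show", "CorrelationResult", function(object) {
    cat("CorrelationResult:", nrow(object@perNMJ), "NMJs, average r =",
        signif(object@averageR, 3), "\n")
})

setMethod("show", "TransientRecording", function(object) {
    cat("TransientRecording:", length(object@time), "samples,",
        length(object@stimulusTimes), "single-AP stimuli",
        if (length(object@train)) "+ train" else "", "\n")
})

setMethod("show", "EphysRecording", function(object) {
    cat("EphysRecording", object@label, ":",
        length(object@mejpAmplitudes), "mEJPs,",
        length(object@ejpAmplitudes), "EJPs, Vrest", object@vRest,
        "mV, Rin", object@rIn, "MOhm\n")
})
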