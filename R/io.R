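## Readers and writers: 16-bit grayscale TIFF (single and multi page),
## CSV tables, JSON sidecars and the YAML run configuration.

#' Read a grayscale TIFF image
#'
#' Reads 8- or 16-bit grayscale TIFFs losslessly as integer-valued
#' matrices. 8-bit input is promoted to the 16-bit range with a recorded
#' flag. RGB or deeper images are rejected.
#'
#' @param path TIFF file.
#' @param pixelSize micrometres per pixel recorded on the frame.
#' @param channel channel label.
#' @return an \linkS4class{ImageFrame}; attribute \code{promoted} on the
#'   pixel matrix is TRUE when 8-bit input was promoted.
#' @export
readImageTIFF <- function(path, pixelSize = 0.1, channel = "") {
    pages <- readTIFFPages(path)
    if (length(pages) != 1)
        stop("expected a single-page TIFF; got ", length(pages),
             " pages in ", path)
    new("ImageFrame", pixels = pages[[1]], pixelSize = pixelSize,
        channel = channel)
}

readTIFFPages <- function(path) {
    raw <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                   info = TRUE),
                    error = function(e)
                        stop("failed reading TIFF '", path, "': ",
                             conditionMessage(e)))
    lapply(seq_along(raw), function(i) {
        m <- raw[[i]]
        if (length(dim(m)) == 3) {
            if (dim(m)[3] == 1) m <- m[, , 1]
            else stop("page ", i, " of '", path,
                      "' is RGB/multichannel; only grayscale is supported")
        }
        bits <- attr(m, "bits.per.sample")
        promoted <- FALSE
        if (!is.null(bits) && bits > 16)
            stop("page ", i, " of '", path, "' has unsupported bit depth ",
                 bits)
        if (!is.null(bits) && bits == 8) {
            m <- m * 257          # 0..255 -> 0..65535
            promoted <- TRUE
        }
        m <- matrix(as.numeric(m), nrow = nrow(m))
        if (promoted) attr(m, "promoted") <- TRUE
        m
    })
}

#' Write a grayscale image as 16-bit TIFF
#'
#' Values are rounded to integers and clipped to [0, 65535]; the written
#' file round-trips bit-identically through \code{\link{readImageTIFF}}.
#'
#' @param image \linkS4class{ImageFrame} or matrix.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeImageTIFF <- function(image, path) {
    px <- asPixels(image)
    px <- pmin(pmax(round(px), 0), 65535)
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
    invisible(path)
}

#' Read a movie from a multi-page TIFF
#'
#' @param path multi-page TIFF, one page per frame in order.
#' @param frameRate frames per second.
#' @param stimFrames 1-based stimulus frame indices.
#' @param baselineFrames 1-based baseline frame indices.
#' @param pixelSize micrometres per pixel.
#' @return an \linkS4class{AZMovie}.
#' @export
readMovieTIFF <- function(path, frameRate, stimFrames,
                          baselineFrames = integer(0), pixelSize = 0.1) {
    frames <- readTIFFPages(path)
    new("AZMovie", frames = frames, frameRate = frameRate,
        stimFrames = as.integer(stimFrames),
        baselineFrames = as.integer(baselineFrames),
        pixelSize = pixelSize)
}

#' Write a movie as a multi-page 16-bit TIFF plus a stimulus-frame CSV
#'
#' @param movie an \linkS4class{AZMovie}.
#' @param path output TIFF; the stimulus log goes to
#'   \code{<path>.stim.csv}.
#' @return invisibly, the TIFF path.
#' @export
writeMovieTIFF <- function(movie, path) {
    pages <- lapply(movie@frames, function(f)
        pmin(pmax(round(f), 0), 65535) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    write.csv(data.frame(stim_frame = movie@stimFrames),
              paste0(path, ".stim.csv"), row.names = FALSE)
    invisible(path)
}

#' Read a run configuration
#'
#' YAML configuration with sections \code{simulate}, \code{puncta},
#' \code{events}, \code{paired} and top-level \code{seed}; unknown keys at
#' either level are rejected so typos fail loudly.
#'
#' @param path YAML file, or a list already in memory.
#' @return validated named list.
#' @export
readRunConfig <- function(path) {
    cfg <- if (is.list(path)) path else yaml::read_yaml(path)
    knownTop <- c("seed", "stages", "simulate", "puncta", "events",
                  "paired")
    known <- list(
        simulate = c("nAZ", "fieldWidth", "fieldHeight", "levelOffset",
                     "nStimuli",
                     "jitterSD", "psfSigma", "background", "gain",
                     "noiseSD", "minSpacing", "framesPerStim",
                     "nBaselineFrames", "flashAmplitude", "decayFrames",
                     "decayRatio", "movieNoiseSD", "pairedMode",
                     "pairedParam", "pairedNoiseCV", "vehicleDrift"),
        puncta = c("noiseTolerance", "minIntensity", "gaussianSigma",
                   "backgroundMethod", "backgroundValue"),
        events = c("threshold", "persistence", "matchRadius"),
        paired = c("relTol", "useCorrected"))
    extra <- setdiff(names(cfg), knownTop)
    if (length(extra))
        stop("unknown config keys: ", paste(extra, collapse = ", "))
    for (sec in names(known)) {
        bad <- setdiff(names(cfg[[sec]]), known[[sec]])
        if (length(bad))
            stop("unknown keys in section '", sec, "': ",
                 paste(bad, collapse = ", "))
    }
    cfg
}
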