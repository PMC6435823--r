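## Quantal analysis of intracellular recordings: recording-quality gates,
## per-recording quantal content and normalized group summaries.

#' Recording quality gate
#'
#' A recording passes when the resting potential lies in [-80, -60] mV,
#' input resistance is >= 5 MOhm, at least 100 mEJPs and at least 20 EJPs
#' were collected.
#'
#' @param recording an \linkS4class{EphysRecording}.
#' @param vRestRange acceptable resting-potential range (mV).
#' @param minRIn minimum input resistance (MOhm).
#' @param minMEJPs,minEJPs minimum event counts.
#' @return logical.
#' @export
recordingQC <- function(recording, vRestRange = c(-80, -60), minRIn = 5,
                        minMEJPs = 100, minEJPs = 20) {
    recording@vRest >= vRestRange[1] && recording@vRest <= vRestRange[2] &&
        recording@rIn >= minRIn &&
        length(recording@mejpAmplitudes) >= minMEJPs &&
        length(recording@ejpAmplitudes) >= minEJPs
}

#' Per-recording quantal content
#'
#' The ratio of the mean EJP amplitude to the mean mEJP amplitude of the
#' same recording. Group statistics must average these per-recording
#' ratios, not take the ratio of group means.
#'
#' @param recording an \linkS4class{EphysRecording}.
#' @param requireQC error when the recording fails
#'   \code{\link{recordingQC}} (default); set FALSE to compute anyway.
#' @return one-row data.frame: label, mean_mejp, mean_ejp,
#'   quantal_content.
#' @export
quantalContent <- function(recording, requireQC = TRUE) {
    if (requireQC && !recordingQC(recording))
        stop("recording '", recording@label, "' fails quality gates")
    mm <- mean(recording@mejpAmplitudes)
    if (!is.finite(mm) || mm == 0) stop("mean mEJP amplitude is zero")
    me <- mean(recording@ejpAmplitudes)
    data.frame(label = recording@label, mean_mejp = mm, mean_ejp = me,
               quantal_content = me / mm)
}

#' Group summary of quantal results
#'
#' Means and SEMs of per-recording quantal content by group, percent of
#' the control-group mean, and normality-gated pairwise tests against
#' control (Student/Welch t or Mann-Whitney U, as in
#' \code{\link{populationCompare}}).
#'
#' @param groups named list of numeric vectors of per-recording quantal
#'   contents (or of data.frames from \code{\link{quantalContent}}).
#' @param control name of the control group.
#' @param alpha alpha for the normality/variance gates.
#' @return data.frame: group, n, mean, sem, percent_of_control,
#'   percent_sem, test, p.value.
#' @export
quantalGroupSummary <- function(groups, control, alpha = 0.05) {
    groups <- lapply(groups, function(g)
        if (is.data.frame(g)) g$quantal_content else g)
    if (!control %in% names(groups))
        stop("unknown control group '", control, "'")
    ctrl <- groups[[control]]
    ctrlMean <- mean(ctrl)
    do.call(rbind, lapply(names(groups), function(g) {
        v <- groups[[g]]
        tst <- if (g == control) list(test = "", p.value = NA_real_)
               else chooseUnpairedTest(v, ctrl, alpha)
        data.frame(group = g, n = length(v), mean = mean(v),
                   sem = sd(v) / sqrt(length(v)),
                   percent_of_control = 100 * mean(v) / ctrlMean,
                   percent_sem = 100 * sd(v) / sqrt(length(v)) / ctrlMean,
                   test = tst$test, p.value = tst$p.value)
    }))
}
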