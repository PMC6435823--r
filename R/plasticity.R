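## Homeostatic-plasticity analyses: vehicle correction of paired intensities,
## paired change testing, additive-versus-multiplicative scaling
## discrimination, tercile change-frequency analysis and population
## comparisons.

#' Correct treated after-values for vehicle-only effects
#'
#' The correction factor f is the mean over vehicle puncta of
#' after_raw / baseline; treated after-values are divided by f. With the
#' synthetic generator and noise off, f equals the generator's
#' vehicle drift exactly, so the correction inverts it.
#'
#' @param treated treated \linkS4class{PairedIntensityTable}.
#' @param vehicle vehicle-only \linkS4class{PairedIntensityTable}
#'   (nonempty, positive baselines).
#' @return the treated table with \code{after_corrected}, \code{delta} and
#'   the correction factor filled in.
#' @export
vehicleCorrect <- function(treated, vehicle) {
    vt <- azTable(vehicle)
    if (!nrow(vt)) stop("vehicle table is empty")
    if (any(vt$baseline <= 0)) stop("vehicle baselines must be positive")
    f <- mean(vt$after_raw / vt$baseline)
    tb <- azTable(treated)
    tb$after_corrected <- tb$after_raw / f
    tb$delta <- tb$after_corrected - tb$baseline
    new("PairedIntensityTable", table = tb, correctionFactor = f,
        group = treated@group)
}

#' Test for a paired intensity change
#'
#' Normality of the per-punctum deltas (D'Agostino-Pearson omnibus, or
#' Shapiro-Wilk when n < 8) selects between a paired t test and the
#' Wilcoxon signed-rank test; both are two-sided. When every delta is
#' exactly zero the degenerate path returns p = 1.
#'
#' @param table \linkS4class{PairedIntensityTable} with >= 6 pairs.
#' @param normalityAlpha alpha of the normality gate.
#' @return list with \code{test}, \code{statistic}, \code{p.value},
#'   \code{n}, \code{normal}.
#' @export
pairedChangeTest <- function(table, normalityAlpha = 0.05) {
    tb <- azTable(table)
    if (nrow(tb) < 6) stop("paired change test requires >= 6 pairs")
    d <- tb$after_corrected - tb$baseline
    if (all(d == 0))
        return(list(test = "degenerate", statistic = NA_real_,
                    p.value = 1, n = length(d), normal = NA))
    normal <- isNormalSample(d, normalityAlpha)
    if (normal) {
        ht <- t.test(d)
        list(test = "paired t", statistic = unname(ht$statistic),
             p.value = ht$p.value, n = length(d), normal = TRUE)
    } else {
        ht <- suppressWarnings(wilcox.test(d))
        list(test = "Wilcoxon signed rank",
             statistic = unname(ht$statistic), p.value = ht$p.value,
             n = length(d), normal = FALSE)
    }
}

#' Discriminate additive from multiplicative scaling
#'
#' Fits three lines to after-versus-baseline intensities: the unconstrained
#' least-squares line (slope, intercept, R-squared, for reference), the
#' one-parameter additive model y = x + c with c the mean delta, and the
#' one-parameter multiplicative model y = m x with the least-squares factor
#' m = sum(xy) / sum(x^2). The constrained models have equal parameter
#' counts, so the lower residual sum of squares wins outright;
#' "indistinguishable" is returned when the RSS difference is within
#' \code{relTol} of the smaller RSS (or both are zero). AIC for both
#' constrained models is reported for transparency.
#'
#' @param table \linkS4class{PairedIntensityTable} with >= 3 puncta and
#'   nonzero baseline variance.
#' @param useCorrected compare vehicle-corrected (default) or raw
#'   after-values against baseline.
#' @param relTol relative RSS tolerance for the indistinguishable call.
#' @return a \linkS4class{ScalingFit}.
#' @export
fitScalingModels <- function(table, useCorrected = TRUE, relTol = 0.02) {
    tb <- azTable(table)
    if (nrow(tb) < 3) stop("scaling fit requires >= 3 puncta")
    x <- tb$baseline
    y <- if (useCorrected) tb$after_corrected else tb$after_raw
    if (sd(x) == 0) stop("zero baseline variance")
    fit <- lm(y ~ x)
    ## HC3 robust slope CI: measurement noise scales with intensity, so
    ## homoscedastic OLS intervals would be anti-conservative
    seR <- sqrt(diag(suppressWarnings(
        sandwich::vcovHC(fit, type = "HC3"))))[2]
    slopeCI <- unname(coef(fit)[2] +
        c(-1, 1) * stats::qt(0.975, fit$df.residual) * seR)
    rss <- function(res) sum(res^2)
    cAdd <- mean(y - x)
    rssAdd <- rss(y - (x + cAdd))
    mMult <- sum(x * y) / sum(x^2)
    rssMult <- rss(y - mMult * x)
    n <- length(x)
    aic <- function(r) n * log(max(r, .Machine$double.eps) / n) + 2
    selected <- if ((rssAdd == 0 && rssMult == 0) ||
                    abs(rssAdd - rssMult) <= relTol * min(rssAdd, rssMult))
        "indistinguishable"
    else if (rssAdd < rssMult) "additive" else "multiplicative"
    new("ScalingFit",
        freeSlope = unname(coef(fit)[2]),
        freeIntercept = unname(coef(fit)[1]),
        rSquared = suppressWarnings(summary(fit)$r.squared),
        freeSlopeCI = slopeCI,
        additiveC = cAdd, rssAdd = rssAdd,
        multiplicativeM = mMult, rssMult = rssMult,
        aicAdd = aic(rssAdd), aicMult = aic(rssMult),
        selected = selected, relTol = relTol, n = as.integer(n))
}

#' Tercile change-frequency analysis
#'
#' Ranks puncta by baseline intensity, splits them into three near-equal
#' groups (bottom / middle / top; sizes differ by at most one, extra
#' members go to the lower terciles; ties broken by stable input order) and
#' reports, per tercile, the proportion of puncta with no change or a
#' decrease (delta <= 0), plus all three pairwise two-sided Fisher exact
#' tests on the 2x2 (delta <= 0 vs > 0) tables.
#'
#' @param table \linkS4class{PairedIntensityTable} with >= 9 puncta.
#' @return a \linkS4class{TercileReport}.
#' @export
tercileChangeAnalysis <- function(table) {
    tb <- azTable(table)
    n <- nrow(tb)
    if (n < 9) stop("tercile analysis requires >= 9 puncta")
    o <- order(tb$baseline)                 # stable for ties
    sizes <- rep(n %/% 3, 3) + c(n %% 3 >= 1, n %% 3 >= 2, FALSE)
    grp <- rep(1:3, times = sizes)
    noch <- (tb$delta <= 0)[o]
    cnt <- tapply(noch, grp, sum)
    rep_tb <- data.frame(tercile = c("bottom", "middle", "top"),
                         n = sizes, n_nochange = as.integer(cnt),
                         prop_nochange = as.numeric(cnt) / sizes)
    pairs <- list(c(1, 2), c(2, 3), c(1, 3))
    fis <- do.call(rbind, lapply(pairs, function(pr) {
        m <- matrix(c(cnt[pr[1]], sizes[pr[1]] - cnt[pr[1]],
                      cnt[pr[2]], sizes[pr[2]] - cnt[pr[2]]),
                    nrow = 2, byrow = TRUE)
        data.frame(comparison = paste(rep_tb$tercile[pr[1]], "vs",
                                      rep_tb$tercile[pr[2]]),
                   p.value = fisher.test(m)$p.value)
    }))
    new("TercileReport", table = rep_tb, fisher = fis, n = as.integer(n))
}

#' Compare population intensity between groups
#'
#' Normalizes per-NMJ mean punctum intensities to the control-group mean
#' and tests each group against control with the normality-gated unpaired
#' test (Student/Welch t or Mann-Whitney U). Optionally emits per-AZ
#' empirical cumulative distributions for plotting.
#'
#' @param groups named list of numeric vectors, one per group, each the
#'   per-NMJ mean punctum intensities (>= 3 NMJs per group).
#' @param normalizeTo name of the control group.
#' @param perAZ optional named list of per-AZ intensity vectors for the
#'   cumulative distributions.
#' @param alpha alpha of the normality/variance gates.
#' @return list with \code{summary} (data.frame: group, n, mean, sem,
#'   normalized_mean, normalized_sem, test, p.value) and \code{cdf}
#'   (data.frame of per-AZ values and cumulative probabilities, or NULL).
#' @export
populationCompare <- function(groups, normalizeTo, perAZ = NULL,
                              alpha = 0.05) {
    if (!normalizeTo %in% names(groups))
        stop("unknown control group '", normalizeTo, "'")
    if (length(groups) < 2) stop("need at least two groups")
    bad <- names(groups)[vapply(groups, length, 1L) < 3]
    if (length(bad))
        stop("each group needs >= 3 NMJs; too few in: ",
             paste(bad, collapse = ", "))
    ctrl <- groups[[normalizeTo]]
    ctrlMean <- mean(ctrl)
    rows <- lapply(names(groups), function(g) {
        v <- groups[[g]]
        if (g == normalizeTo) {
            tst <- list(test = "", p.value = NA_real_)
        } else tst <- chooseUnpairedTest(v, ctrl, alpha)
        data.frame(group = g, n = length(v), mean = mean(v),
                   sem = sd(v) / sqrt(length(v)),
                   normalized_mean = mean(v) / ctrlMean,
                   normalized_sem = sd(v) / sqrt(length(v)) / ctrlMean,
                   test = tst$test, p.value = tst$p.value)
    })
    cdf <- NULL
    if (!is.null(perAZ)) {
        cdf <- do.call(rbind, lapply(names(perAZ), function(g) {
            v <- sort(perAZ[[g]])
            data.frame(group = g, intensity = v,
                       cumulative = seq_along(v) / length(v))
        }))
    }
    list(summary = do.call(rbind, rows), cdf = cdf)
}

#' Plot a scaling fit
#'
#' After-versus-baseline scatter with the unity line, the fitted additive
#' and multiplicative lines, and the unconstrained least-squares line.
#'
#' @param fit a \linkS4class{ScalingFit}.
#' @param table the \linkS4class{PairedIntensityTable} it was fitted to.
#' @param useCorrected which after-values to plot.
#' @return invisibly, NULL; draws on the current device.
#' @export
plotScalingFit <- function(fit, table, useCorrected = TRUE) {
    tb <- azTable(table)
    y <- if (useCorrected) tb$after_corrected else tb$after_raw
    graphics::plot(tb$baseline, y, pch = 16, cex = 0.6,
                   col = grDevices::grey(0.3, 0.5),
                   xlab = "baseline intensity (a.u.)",
                   ylab = "after intensity (a.u.)")
    graphics::abline(0, 1, lty = 3)
    graphics::abline(fit@additiveC, 1, col = "darkgreen")
    graphics::abline(0, fit@multiplicativeM, col = "darkorange")
    graphics::abline(fit@freeIntercept, fit@freeSlope, col = "steelblue")
    graphics::legend("topleft", bty = "n",
        legend = c("unity", sprintf("additive c=%.2f", fit@additiveC),
                   sprintf("multiplicative m=%.2f", fit@multiplicativeM),
                   sprintf("free fit slope=%.2f", fit@freeSlope)),
        col = c("black", "darkgreen", "darkorange", "steelblue"),
        lty = c(3, 1, 1, 1))
    invisible(NULL)
}
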