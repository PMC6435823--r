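## Normality gating and test selection shared by the paired and population
## comparison routines.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe-Glynn 1983) into the K-squared omnibus statistic, referred to a
#' chi-squared distribution with 2 degrees of freedom. Requires n >= 8.
#'
#' @param x numeric vector (n >= 8).
#' @return list with \code{statistic} (K-squared), \code{p.value},
#'   \code{z.skew}, \code{z.kurt}.
#' @export
dagostinoPearsonTest <- function(x) {
    n <- length(x)
    if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
    x <- x - mean(x)
    m2 <- mean(x^2); m3 <- mean(x^3); m4 <- mean(x^4)
    b1 <- m3 / m2^1.5                       # sqrt(b1), sample skewness
    b2 <- m4 / m2^2                         # sample kurtosis
    ## skewness z (D'Agostino 1970)
    y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
    if (y == 0) y <- 1   # original algorithm's zero-skew convention
    beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
        ((n - 2) * (n + 5) * (n + 7) * (n + 9))
    W2 <- -1 + sqrt(2 * (beta2 - 1))
    delta <- 1 / sqrt(log(sqrt(W2)))
    alpha <- sqrt(2 / (W2 - 1))
    zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
    ## kurtosis z (Anscombe-Glynn 1983)
    eb2 <- 3 * (n - 1) / (n + 1)
    vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
    stdb2 <- (b2 - eb2) / sqrt(vb2)
    beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
        sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
    A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
    denom <- 1 + stdb2 * sqrt(2 / (A - 4))
    term <- sign(denom) * abs((1 - 2 / A) / denom)^(1 / 3)
    zk <- ((1 - 2 / (9 * A)) - term) / sqrt(2 / (9 * A))
    K2 <- zs^2 + zk^2
    list(statistic = K2, p.value = pchisq(K2, df = 2, lower.tail = FALSE),
         z.skew = zs, z.kurt = zk)
}

## normality gate: D'Agostino-Pearson where its n >= 8 requirement is met,
## Shapiro-Wilk for smaller samples
isNormalSample <- function(x, alpha = 0.05) {
    if (sd(x) == 0) return(FALSE)
    p <- if (length(x) >= 8) dagostinoPearsonTest(x)$p.value
         else shapiro.test(x)$p.value
    p > alpha
}

## two-group unpaired test selection: Student's t when both samples pass the
## normality gate (Welch's correction under unequal variances by F test),
## Mann-Whitney U otherwise
chooseUnpairedTest <- function(x, y, alpha = 0.05) {
    if (isNormalSample(x, alpha) && isNormalSample(y, alpha)) {
        equalVar <- var.test(x, y)$p.value > alpha
        ht <- t.test(x, y, var.equal = equalVar)
        list(test = if (equalVar) "Student t" else "Welch t",
             statistic = unname(ht$statistic), p.value = ht$p.value)
    } else {
        ht <- suppressWarnings(wilcox.test(x, y))
        list(test = "Mann-Whitney U", statistic = unname(ht$statistic),
             p.value = ht$p.value)
    }
}
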