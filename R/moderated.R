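## Empirical-Bayes moderated two-group t-test with BH FDR control.
##
## The per-probeset residual variances are modelled as draws from a scaled
## inverse-chi-square prior (d0, s0^2); the posterior variance blends each
## probeset's own variance with the prior, weighted by degrees of freedom,
## which stabilizes the t-statistic at the tiny replicate numbers common in
## tissue compendia (several groups here have n = 2).

.VAR_FLOOR <- 1e-8

## invert trigamma by Newton iteration; monotone decreasing on (0, Inf)
.trigammaInverse <- function(y) {
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    x <- 0.5 + 1 / y
    for (i in seq_len(50L)) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
        x <- x + dif
        if (abs(dif) / x < 1e-10) break
    }
    x
}

#' Fit the variance prior across probesets
#'
#' Method-of-moments fit of a scaled inverse-chi-square prior to observed
#' per-probeset sample variances, performed on the log scale: the mean and
#' variance of `log(s2)` are matched to their theoretical values under the
#' prior, using digamma/trigamma corrections for the residual degrees of
#' freedom. When the empirical spread of the log-variances does not exceed
#' its pure sampling expectation, the prior degrees of freedom are infinite
#' (complete shrinkage to a common variance).
#'
#' Zero variances are floored at `1e-8` to keep log-variances finite.
#'
#' @param s2 numeric vector of per-probeset sample variances (>= 0).
#' @param df residual degrees of freedom, scalar or per-probeset (>= 1).
#' @return a [PriorEstimate-class].
#' @examples
#' set.seed(1)
#' s2 <- 4 * 0.05 / rchisq(1000, df = 4) * rchisq(1000, df = 6) / 6
#' estimateVariancePrior(s2, df = 6)
#' @export
estimateVariancePrior <- function(s2, df) {
    if (any(is.na(s2)) || any(s2 < 0))
        stop("variances must be nonnegative and non-missing")
    df <- rep_len(df, length(s2))
    use <- df >= 1
    if (sum(use) < 10L)
        stop("insufficient data: need >= 10 probesets with df >= 1")
    s2 <- pmax(s2[use], .VAR_FLOOR)
    df <- df[use]
    z <- log(s2)
    e <- z - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- var(e) - mean(trigamma(df / 2))
    ## no spread beyond sampling noise: common variance, estimated by the
    ## arithmetic mean of the sample variances
    if (!is.finite(evar) || evar <= 0)
        return(priorEstimate(Inf, mean(s2)))
    d0 <- 2 * .trigammaInverse(evar)
    s0Sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    priorEstimate(d0, s0Sq)
}

#' Moderated two-group t-test
#'
#' For each probeset, computes the log2 mean difference `mean(a) - mean(b)`,
#' the pooled sample variance with `df = n_a + n_b - 2`, the posterior
#' variance `(d0*s0Sq + df*s2) / (d0 + df)`, the moderated t-statistic
#' `diff / sqrt(s2_post * (1/n_a + 1/n_b))`, a two-sided p-value from the
#' Student t distribution with `d0 + df` degrees of freedom (standard normal
#' when `d0` is infinite), and the Benjamini-Hochberg adjusted q-value across
#' the probesets of this contrast. With `d0 = 0` the statistic reduces to the
#' classical pooled two-sample t.
#'
#' Groups with fewer than 2 samples carry no residual information; by default
#' this is an error. With `smallGroupFallback = TRUE` and an externally
#' estimated prior, such probesets are tested against the prior variance
#' alone (`df = 0`, t referred to `d0` degrees of freedom) and flagged
#' `prior_only` — minimal-replication groups must not crash the screen, but
#' their calls are visibly weaker.
#'
#' @param a,b numeric matrices (probesets x samples), identical row sets, one
#'   per group; a contrast of a vs b (positive t = higher in `a`).
#' @param prior a [PriorEstimate-class]; fitted from this contrast's pooled
#'   variances when `NULL`.
#' @param smallGroupFallback allow groups with < 2 samples (needs `prior`).
#' @return data.frame with columns `probeset_id`, `log2fc`, `s2`, `df`,
#'   `s2_post`, `df_total`, `t`, `p`, `q`, `method_flag`.
#' @export
moderatedTTest <- function(a, b, prior = NULL, smallGroupFallback = FALSE) {
    if (!is.matrix(a) || !is.matrix(b) || nrow(a) != nrow(b))
        stop("a and b must be matrices over the same probesets")
    if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
        !identical(rownames(a), rownames(b)))
        stop("a and b have different probeset row names")
    na <- ncol(a); nb <- ncol(b)
    if (na < 1L || nb < 1L) stop("each group needs at least one sample")
    dg <- max(na - 1L, 0L) + max(nb - 1L, 0L)
    small <- na < 2L || nb < 2L
    if (small && !smallGroupFallback)
        stop("a group has < 2 samples; rerun with smallGroupFallback = TRUE ",
             "and an externally estimated prior")
    if (small && is.null(prior))
        stop("smallGroupFallback requires an externally estimated prior")
    am <- rowMeans(a); bm <- rowMeans(b)
    diff <- am - bm
    if (dg >= 1L) {
        rss <- rowSums((a - am)^2) + rowSums((b - bm)^2)
        s2 <- rss / dg
    } else {
        s2 <- rep(NA_real_, nrow(a))
    }
    if (small) {
        ## no pooled residual: prior variance only
        dfg <- 0
        s2use <- rep(0, nrow(a))
        flag <- "prior_only"
    } else {
        dfg <- dg
        s2use <- s2
        flag <- "moderated"
    }
    if (is.null(prior)) prior <- estimateVariancePrior(s2use, dfg)
    d0 <- priorDf(prior); s0 <- priorVar(prior)
    s2post <- if (is.infinite(d0)) rep(s0, nrow(a))
              else if (d0 == 0) pmax(s2use, .VAR_FLOOR)
              else (d0 * s0 + dfg * s2use) / (d0 + dfg)
    if (dfg == 0 && d0 == 0)
        stop("no residual degrees of freedom and d0 = 0: statistic undefined")
    se <- sqrt(s2post * (1 / na + 1 / nb))
    tstat <- diff / se
    dfTotal <- d0 + dfg
    p <- if (is.infinite(dfTotal)) 2 * pnorm(-abs(tstat))
         else 2 * pt(-abs(tstat), df = dfTotal)
    ids <- rownames(a)
    if (is.null(ids)) ids <- paste0("ps", seq_len(nrow(a)))
    data.frame(probeset_id = ids,
               log2fc = unname(diff),
               s2 = unname(if (small) rep(NA_real_, nrow(a)) else s2),
               df = dfg,
               s2_post = unname(s2post),
               df_total = dfTotal,
               t = unname(tstat),
               p = unname(p),
               q = benjaminiHochberg(unname(p)),
               method_flag = flag,
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_(j >= i) p_(j) * n / j` over the ascending-sorted p-values,
#' capped at 1 and returned in the original order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjaminiHochberg <- function(p) {
    if (length(p) == 0L) return(numeric(0))
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    q[order(o)]
}

#' Write a contrast result table as TSV
#'
#' Columns `probeset_id, log2fc, t, p, q, method_flag`.
#'
#' @param contrast data.frame from [moderatedTTest()].
#' @param path output path.
#' @export
writeContrastResult <- function(contrast, path) {
    .writeTsv(contrast[c("probeset_id", "log2fc", "t", "p", "q",
                         "method_flag")], path)
}
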