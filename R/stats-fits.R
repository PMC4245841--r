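#' @importFrom stats dgamma dweibull rgamma rexp rweibull runif uniroot logLik
#'   setNames var sd
NULL

#' Distances between adjacent variants
#'
#' Positions on one chromosome are sorted and differenced. Distance zero
#' (co-located records) has no density mass under the continuous families
#' fitted here, so zeros are dropped by default; alternatively they can be
#' retained with a +0.5 offset.
#'
#' @param positions integer vector of variant positions on one chromosome
#'   (at least 2).
#' @param dropZero drop zero distances (default `TRUE`). When `FALSE`,
#'   zero distances are replaced by 0.5.
#' @return numeric vector of adjacent distances in base pairs.
#' @export
adjacentDistances <- function(positions, dropZero = TRUE) {
    if (length(positions) < 2L)
        stop("need at least 2 positions to form adjacent distances")
    d <- diff(sort(as.numeric(positions)))
    if (dropZero) d[d > 0] else ifelse(d == 0, 0.5, d)
}

.fit_result <- function(family, estimate, n, logLik) {
    new("FitResult", family = family, estimate = estimate,
        n = as.integer(n), logLik = logLik)
}

#' Fit a Pareto distribution with location fixed at 1
#'
#' Indel sizes have minimum value 1, so the Pareto location (scale)
#' parameter is fixed there and only the shape is estimated. The MLE is
#' closed form: `shape = n / sum(log(x))`, with log-likelihood
#' `n*log(shape) - (shape + 1) * sum(log(x))`.
#'
#' @param x numeric values >= 1 (indel sizes in bp).
#' @return a [FitResult-class] with estimate `shape`.
#' @export
fitPareto <- function(x) {
    x <- as.numeric(x)
    if (length(x) < 1L || any(x < 1)) stop("sizes must be >= 1")
    sumlog <- sum(log(x))
    if (sumlog <= 0)
        stop("shape MLE diverges: all values equal 1")
    n <- length(x)
    shape <- n / sumlog
    .fit_result("pareto", c(shape = shape), n,
                n * log(shape) - (shape + 1) * sumlog)
}

#' Fit a Gamma distribution by maximum likelihood
#'
#' The shape solves the profile equation
#' `log(a) - digamma(a) = log(mean(x)) - mean(log(x))`, found by Newton
#' iteration in `log(a)` from the moment start `a0 = 0.5 / s` (bisection
#' fallback if Newton leaves `(0, Inf)`); convergence when the log-shape
#' step falls below 1e-10 or after 200 iterations. The rate is then
#' `shape / mean(x)`, so the fitted mean equals the sample mean exactly.
#'
#' @param x positive distances (at least 2, non-zero variance).
#' @return a [FitResult-class] with estimates `shape`, `rate`.
#' @export
fitGamma <- function(x) {
    x <- as.numeric(x)
    if (length(x) < 2L) stop("need at least 2 values")
    if (any(x <= 0)) stop("values must be positive")
    if (var(x) == 0) stop("zero variance: Gamma fit is degenerate")
    s <- log(mean(x)) - mean(log(x))   # > 0 by Jensen for non-constant x
    h <- function(a) log(a) - digamma(a) - s
    a <- 0.5 / s
    for (iter in seq_len(200L)) {
        # d h / d log(a) = 1 - a * trigamma(a), strictly negative
        step <- h(a) / (1 - a * trigamma(a))
        anew <- exp(log(a) - step)
        if (!is.finite(anew) || anew <= 0) {
            # bisection fallback on a bracketing interval
            lo <- a; hi <- a
            while (h(lo) < 0) lo <- lo / 2
            while (h(hi) > 0) hi <- hi * 2
            anew <- uniroot(h, c(lo, hi), tol = 1e-12)$root
            a <- anew
            break
        }
        done <- abs(log(anew) - log(a)) < 1e-10
        a <- anew
        if (done) break
    }
    rate <- a / mean(x)
    .fit_result("gamma", c(shape = a, rate = rate), length(x),
                sum(dgamma(x, shape = a, rate = rate, log = TRUE)))
}

#' Fit an exponential distribution by maximum likelihood
#'
#' `rate = 1 / mean(x)`; log-likelihood `n*log(rate) - rate*sum(x)`.
#'
#' @param x positive distances.
#' @return a [FitResult-class] with estimate `rate`.
#' @export
fitExponential <- function(x) {
    x <- as.numeric(x)
    if (length(x) < 1L || any(x <= 0)) stop("values must be positive")
    n <- length(x)
    rate <- 1 / mean(x)
    .fit_result("exponential", c(rate = rate), n,
                n * log(rate) - rate * sum(x))
}

#' Fit a Weibull distribution by maximum likelihood
#'
#' The scale is eliminated analytically; the shape solves the standard
#' profile equation
#' `sum(x^k log x)/sum(x^k) - 1/k - mean(log x) = 0`, located by bracket
#' expansion and `uniroot`. The profile weights are computed on
#' `x/max(x)` for overflow safety (they are scale-invariant).
#'
#' @param x positive distances (at least 2, non-zero variance).
#' @return a [FitResult-class] with estimates `shape`, `scale`.
#' @export
fitWeibull <- function(x) {
    x <- as.numeric(x)
    if (length(x) < 2L) stop("need at least 2 values")
    if (any(x <= 0)) stop("values must be positive")
    if (var(x) == 0) stop("zero variance: Weibull fit is degenerate")
    lx <- log(x)
    mlx <- mean(lx)
    xs <- x / max(x)
    g <- function(k) {
        w <- xs^k
        sum(w * lx) / sum(w) - 1 / k - mlx
    }
    lo <- 1e-3
    hi <- 1
    it <- 0L
    while (g(lo) > 0 && it < 60L) { lo <- lo / 2; it <- it + 1L }
    it <- 0L
    while (g(hi) < 0 && it < 200L) { hi <- hi * 2; it <- it + 1L }
    if (g(lo) > 0 || g(hi) < 0)
        stop("Weibull shape search failed to bracket a root (g(",
             format(lo), ") = ", format(g(lo)), ", g(", format(hi),
             ") = ", format(g(hi)), ")")
    k <- uniroot(g, c(lo, hi), tol = 1e-12)$root
    scale <- mean(x^k)^(1 / k)
    .fit_result("weibull", c(shape = k, scale = scale), length(x),
                sum(dweibull(x, shape = k, scale = scale, log = TRUE)))
}

#' Fit one of the supported families
#'
#' @param x sample values.
#' @param family `"pareto"`, `"gamma"`, `"exponential"` or `"weibull"`.
#' @return a [FitResult-class].
#' @export
fitDistribution <- function(x, family = c("pareto", "gamma",
                                          "exponential", "weibull")) {
    family <- match.arg(family)
    switch(family,
           pareto = fitPareto(x),
           gamma = fitGamma(x),
           exponential = fitExponential(x),
           weibull = fitWeibull(x))
}

#' Mean and variance ratios of two Gamma fits
#'
#' For Gamma fits to adjacent-indel and adjacent-SNP distances, compares
#' the fitted means (`shape/rate`) and variances (`shape/rate^2`). On
#' genome-wide catalogues the adjacent-indel mean is roughly an order of
#' magnitude larger than the adjacent-SNP mean, consistent with the lower
#' indel mutation rate.
#'
#' @param fitIndel,fitSnp [FitResult-class] objects of family `"gamma"`.
#' @return named numeric vector `c(mean_ratio, variance_ratio)`.
#' @export
gammaMeanVarianceRatio <- function(fitIndel, fitSnp) {
    if (fitFamily(fitIndel) != "gamma" || fitFamily(fitSnp) != "gamma")
        stop("both fits must be of the gamma family")
    ei <- fitEstimate(fitIndel)
    es <- fitEstimate(fitSnp)
    c(mean_ratio = (ei[["shape"]] / ei[["rate"]]) /
          (es[["shape"]] / es[["rate"]]),
      variance_ratio = (ei[["shape"]] / ei[["rate"]]^2) /
          (es[["shape"]] / es[["rate"]]^2))
}

#' Integer-binned size histogram with an overflow bin
#'
#' @param x integer sizes >= 1.
#' @param maxBin largest individually binned size; larger values pool into
#'   the overflow bin.
#' @return data.frame with columns `bin` (`"1"` .. `maxBin`, then
#'   `">maxBin"`) and `count`; counts sum to `length(x)`.
#' @export
sizeHistogram <- function(x, maxBin) {
    stopifnot(maxBin >= 1L)
    x <- as.integer(x)
    stopifnot(all(x >= 1L))
    counts <- tabulate(pmin(x, maxBin + 1L), nbins = maxBin + 1L)
    data.frame(bin = c(as.character(seq_len(maxBin)),
                       paste0(">", maxBin)),
               count = counts)
}

#' Serialise fit results to JSON and a key-value block
#'
#' @param fits a list of [FitResult-class] objects (possibly named).
#' @param jsonPath optional path for machine-readable JSON.
#' @return character vector of key-value lines, invisibly if written.
#' @export
formatFits <- function(fits, jsonPath = NULL) {
    if (is(fits, "FitResult")) fits <- list(fits)
    lines <- unlist(lapply(fits, function(f) {
        est <- fitEstimate(f)
        c(sprintf("family\t%s", fitFamily(f)),
          sprintf("%s\t%.10g", names(est), est),
          sprintf("n\t%d", f@n),
          sprintf("loglik\t%.10g", f@logLik))
    }))
    if (!is.null(jsonPath)) {
        payload <- lapply(fits, function(f)
            list(family = fitFamily(f),
                 params = as.list(fitEstimate(f)),
                 n = f@n, loglik = f@logLik))
        jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE,
                             digits = NA)
    }
    lines
}
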