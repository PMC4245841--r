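test_that("adjacent distances sort, difference and drop zeros", {
    expect_equal(adjacentDistances(c(5, 6, 10)), c(1, 4))
    expect_equal(adjacentDistances(c(10, 5, 6)), c(1, 4))
    expect_equal(adjacentDistances(c(5, 5, 6)), 1)
    expect_equal(adjacentDistances(c(5, 5, 6), dropZero = FALSE), c(0.5, 1))
    expect_error(adjacentDistances(7), "at least 2")
})

test_that("Pareto shape MLE is closed form and matches numeric optimisation", {
    f <- fitPareto(c(2, 2))
    expect_equal(unname(fitEstimate(f)), 1 / log(2), tolerance = 1e-12)
    expect_equal(f@logLik,
                 2 * log(1 / log(2)) - (1 / log(2) + 1) * 2 * log(2))
    expect_error(fitPareto(c(1, 1, 1)), "diverges")
    expect_error(fitPareto(c(0.5, 2)), ">= 1")

    # closed form agrees with direct likelihood maximisation
    set.seed(501)
    for (shape in c(0.7, 1.43, 3)) {
        x <- sampleDistribution("pareto", list(shape = shape), 500,
                                seed = round(shape * 100))
        ll <- function(a) length(x) * log(a) - (a + 1) * sum(log(x))
        num <- optimize(ll, c(1e-3, 50), maximum = TRUE, tol = 1e-10)$maximum
        expect_equal(unname(fitEstimate(fitPareto(x))), num,
                     tolerance = 1e-6)
    }
})

test_that("Gamma MLE solves the digamma profile equation", {
    x <- sampleDistribution("gamma", list(shape = 0.7, rate = 0.01),
                            20000, seed = 77)
    f <- fitGamma(x)
    est <- fitEstimate(f)
    # stationarity of the profile equation at the solution
    s <- log(mean(x)) - mean(log(x))
    expect_equal(log(est[["shape"]]) - digamma(est[["shape"]]), s,
                 tolerance = 1e-8)
    # MLE identity: fitted mean equals the sample mean exactly
    expect_equal(est[["shape"]] / est[["rate"]], mean(x),
                 tolerance = 1e-12)
    # independent cross-check against fitdistrplus
    fd <- fitdistrplus::fitdist(x, "gamma", method = "mle")
    expect_equal(est[["shape"]], unname(fd$estimate["shape"]),
                 tolerance = 2e-3)
    expect_equal(est[["rate"]], unname(fd$estimate["rate"]),
                 tolerance = 2e-3)
    expect_equal(f@logLik, fd$loglik, tolerance = 1e-6)

    expect_error(fitGamma(c(5, 5, 5)), "variance")
    expect_error(fitGamma(c(-1, 2)), "positive")
    expect_error(fitGamma(3), "at least 2")
})

test_that("Gamma nests the exponential on exponential data", {
    x <- sampleDistribution("exponential", list(rate = 0.02),
                            50000, seed = 88)
    fg <- fitGamma(x)
    fe <- fitExponential(x)
    expect_equal(fitEstimate(fg)[["shape"]], 1, tolerance = 0.03)
    expect_gte(fg@logLik, fe@logLik)                 # nested families
    expect_lt((fg@logLik - fe@logLik) / length(x), 0.01)
})

test_that("exponential MLE is the reciprocal sample mean", {
    f <- fitExponential(c(10, 30))
    expect_equal(unname(fitEstimate(f)), 0.05)
    expect_equal(unname(fitEstimate(fitExponential(rep(4, 5)))), 0.25)
    expect_equal(f@logLik, 2 * log(0.05) - 0.05 * 40)
})

test_that("Weibull profile MLE matches the reference optimiser", {
    x <- sampleDistribution("weibull", list(shape = 0.52, scale = 257.43),
                            20000, seed = 99)
    f <- fitWeibull(x)
    est <- fitEstimate(f)
    fd <- fitdistrplus::fitdist(x, "weibull", method = "mle")
    expect_equal(est[["shape"]], unname(fd$estimate["shape"]),
                 tolerance = 1e-3)
    expect_equal(est[["scale"]], unname(fd$estimate["scale"]),
                 tolerance = 1e-3)
    expect_gte(f@logLik, fd$loglik - 1e-4)           # at least as good

    # exponential data: Weibull shape tends to 1, scale to the mean
    xe <- sampleDistribution("exponential", list(rate = 0.02),
                             50000, seed = 100)
    fe <- fitWeibull(xe)
    expect_equal(fitEstimate(fe)[["shape"]], 1, tolerance = 0.03)
    expect_equal(fitEstimate(fe)[["scale"]], 50, tolerance = 0.05 * 50)

    expect_error(fitWeibull(rep(3, 10)), "variance")
})

test_that("each family's log-likelihood is locally optimal at the MLE", {
    dens <- list(
        pareto = function(x, p) length(x) * log(p[["shape"]]) -
            (p[["shape"]] + 1) * sum(log(x)),
        gamma = function(x, p) sum(dgamma(x, shape = p[["shape"]],
                                          rate = p[["rate"]], log = TRUE)),
        exponential = function(x, p) sum(dexp(x, rate = p[["rate"]],
                                              log = TRUE)),
        weibull = function(x, p) sum(dweibull(x, shape = p[["shape"]],
                                              scale = p[["scale"]],
                                              log = TRUE)))
    samples <- list(
        pareto = sampleDistribution("pareto", list(shape = 1.4), 2000, 61),
        gamma = sampleDistribution("gamma", list(shape = 0.5, rate = 0.002),
                                   2000, 62),
        exponential = sampleDistribution("exponential", list(rate = 0.02),
                                         2000, 63),
        weibull = sampleDistribution("weibull",
                                     list(shape = 0.6, scale = 100),
                                     2000, 64))
    for (fam in names(samples)) {
        x <- samples[[fam]]
        f <- fitDistribution(x, fam)
        est <- fitEstimate(f)
        for (pname in names(est)) for (mult in c(0.9, 1.1)) {
            pert <- est
            pert[[pname]] <- pert[[pname]] * mult
            expect_lte(dens[[fam]](x, pert), f@logLik,
                       label = sprintf("%s %s x%.1f", fam, pname, mult))
        }
    }
})

test_that("Gamma mean and variance ratios follow the fitted parameters", {
    fi <- fitGamma(sampleDistribution("gamma",
                                      list(shape = 0.4, rate = 8.09e-4),
                                      5000, 71))
    expect_equal(unname(gammaMeanVarianceRatio(fi, fi)), c(1, 1))
    fs <- fitGamma(sampleDistribution("gamma",
                                      list(shape = 0.86, rate = 0.017),
                                      5000, 72))
    r <- gammaMeanVarianceRatio(fi, fs)
    ei <- fitEstimate(fi); es <- fitEstimate(fs)
    expect_equal(r[["mean_ratio"]],
                 (ei[["shape"]] / ei[["rate"]]) / (es[["shape"]] / es[["rate"]]))
    expect_error(gammaMeanVarianceRatio(fi, fitExponential(c(1, 2))),
                 "gamma")
})

test_that("size histograms bin integers with overflow, conserving counts", {
    h <- sizeHistogram(c(1, 1, 2, 5), 3)
    expect_equal(h$count[h$bin == "1"], 2L)
    expect_equal(h$count[h$bin == "2"], 1L)
    expect_equal(h$count[h$bin == "3"], 0L)
    expect_equal(h$count[h$bin == ">3"], 1L)
    expect_equal(sum(h$count), 4L)
    h0 <- sizeHistogram(integer(0), 5)
    expect_equal(sum(h0$count), 0L)
    set.seed(81)
    x <- sample.int(30, 200, replace = TRUE)
    expect_equal(sum(sizeHistogram(x, 10)$count), 200L)
})
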