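test_that("Benjamini-Hochberg matches the hand-evaluated step-up formula", {
    expect_equal(benjaminiHochberg(0.03), 0.03)
    expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
                 rep(0.04, 4))
    expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
    expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
    ## property vs the reference implementation, and q >= p
    set.seed(4)
    for (i in 1:20) {
        p <- runif(sample(1:50, 1))
        q <- benjaminiHochberg(p)
        expect_equal(q, stats::p.adjust(p, "BH"))
        expect_true(all(q >= p))
        expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
})

test_that("variance prior fit is scale-equivariant and degenerates to d0 = Inf", {
    set.seed(5)
    s2 <- rep(0.04, 50)   # identical variances, large df: no excess spread
    pr <- estimateVariancePrior(s2, df = 50)
    expect_true(is.infinite(priorDf(pr)))
    expect_equal(priorVar(pr), 0.04)
    ## doubling every variance doubles s0Sq and leaves d0 unchanged
    s2b <- 4 * 0.05 / rchisq(5000, df = 4) * rchisq(5000, df = 6) / 6
    pr1 <- estimateVariancePrior(s2b, 6)
    pr2 <- estimateVariancePrior(2 * s2b, 6)
    expect_equal(priorDf(pr2), priorDf(pr1), tolerance = 1e-10)
    expect_equal(priorVar(pr2), 2 * priorVar(pr1), tolerance = 1e-10)
    expect_error(estimateVariancePrior(s2b[1:5], 6), "insufficient")
    ## zero variances are floored, not fatal
    expect_s4_class(estimateVariancePrior(c(rep(0, 6), s2b[1:20]), 6),
                    "PriorEstimate")
})

test_that("prior hyperparameters are recovered from simulated variances", {
    set.seed(6)
    d0 <- 4; s0 <- 0.05; dg <- 6
    sigma2 <- d0 * s0 / rchisq(1e4, df = d0)
    s2 <- sigma2 * rchisq(1e4, df = dg) / dg
    pr <- estimateVariancePrior(s2, dg)
    expect_lt(abs(priorDf(pr) - d0) / d0, 0.20)
    expect_lt(abs(priorVar(pr) - s0) / s0, 0.10)
})

test_that("prior fit and moderated t agree with the limma reference", {
    ## heterogeneous true variances so the prior df comes out finite
    set.seed(7)
    n <- 500
    sd_g <- sqrt(4 * 0.25 / rchisq(n, df = 4))
    a <- matrix(rnorm(n * 4, 0, sd_g), n)
    b <- matrix(rnorm(n * 3, 0, sd_g), n)
    b[1:25, ] <- b[1:25, ] + 1.5
    res <- moderatedTTest(a, b)
    design <- cbind(1, c(rep(1, 4), rep(0, 3)))
    fit <- limma::eBayes(limma::lmFit(cbind(a, b), design))
    expect_true(is.finite(fit$df.prior))
    expect_equal(res$df_total[1] - 5, unname(fit$df.prior), tolerance = 1e-8)
    expect_equal(unname(res$t), unname(fit$t[, 2]), tolerance = 1e-8)
    expect_equal(unname(res$p), unname(fit$p.value[, 2]), tolerance = 1e-8)
    expect_equal(unname(res$log2fc), unname(fit$coefficients[, 2]),
                 tolerance = 1e-10)
    ## homogeneous variances: both fits collapse to a common variance equal
    ## to the mean sample variance
    set.seed(8)
    a2 <- matrix(rnorm(n * 4, 0, 0.5), n)
    b2 <- matrix(rnorm(n * 3, 0, 0.5), n)
    res2 <- moderatedTTest(a2, b2)
    sq <- limma::squeezeVar(res2$s2, 5)
    expect_true(all(is.infinite(res2$df_total)))
    expect_equal(res2$s2_post[1], unname(sq$var.post[1]), tolerance = 1e-10)
})

test_that("d0 = 0 reduces the moderated t to the classical pooled t", {
    set.seed(8)
    a <- matrix(rnorm(5 * 3, 5), 5)
    b <- matrix(rnorm(5 * 4, 5.5), 5)
    res <- moderatedTTest(a, b, prior = priorEstimate(0, 1))
    oracle <- classicalPooledT(a, b)
    expect_equal(res$t, oracle$t, tolerance = 1e-10)
    expect_equal(res$p, oracle$p, tolerance = 1e-10)
})

test_that("moderated t is antisymmetric and null-calibrated", {
    set.seed(9)
    a <- matrix(rnorm(2000 * 3, 5, 0.3), 2000)
    b <- matrix(rnorm(2000 * 3, 5, 0.3), 2000)
    res <- moderatedTTest(a, b)
    swapped <- moderatedTTest(b, a)
    expect_equal(swapped$t, -res$t)
    expect_equal(swapped$p, res$p)
    expect_true(all(res$q >= res$p))
    expect_true(all(res$s2_post > 0))
    ## identical groups give t = 0, p = 1
    same <- moderatedTTest(a, a)
    expect_equal(same$t, rep(0, 2000))
    expect_equal(same$p, rep(1, 2000))
    ## global-null p-values are uniform (Kolmogorov-Smirnov at level 0.01)
    expect_gt(suppressWarnings(stats::ks.test(res$p, "punif"))$p.value, 0.01)
})

test_that("d0 -> Inf limit pins the posterior variance at the prior", {
    set.seed(10)
    a <- matrix(rnorm(20 * 3, 5), 20)
    b <- matrix(rnorm(20 * 3, 6), 20)
    s0 <- 0.2
    res <- moderatedTTest(a, b, prior = priorEstimate(Inf, s0))
    expect_equal(res$s2_post, rep(s0, 20))
    expect_equal(res$t,
                 (rowMeans(a) - rowMeans(b)) / sqrt(s0 * (1 / 3 + 1 / 3)),
                 tolerance = 1e-12)
    expect_equal(res$p, 2 * pnorm(-abs(res$t)))
})

test_that("moderation beats the classical t at small n with planted shifts", {
    set.seed(12)
    n <- 2000; shifted <- seq_len(0.05 * n)
    a <- matrix(rnorm(n * 3, 5, 0.3), n)
    b <- matrix(rnorm(n * 3, 5, 0.3), n)
    a[shifted, ] <- a[shifted, ] + 1.5
    mod <- moderatedTTest(a, b)
    cls <- classicalPooledT(a, b)
    qCls <- benjaminiHochberg(cls$p)
    hitMod <- mean(mod$q[shifted] <= 0.01)
    hitCls <- mean(qCls[shifted] <= 0.01)
    expect_gt(hitMod, hitCls)
    expect_gt(hitMod, 0.9)
})

test_that("groups without replication need the explicit fallback", {
    set.seed(13)
    a <- matrix(rnorm(30, 7), 30, 1)
    b <- matrix(rnorm(90, 5), 30, 3)
    expect_error(moderatedTTest(a, b), "smallGroupFallback")
    expect_error(moderatedTTest(a, b, smallGroupFallback = TRUE), "prior")
    res <- moderatedTTest(a, b, prior = priorEstimate(10, 0.5),
                          smallGroupFallback = TRUE)
    expect_true(all(res$method_flag == "prior_only"))
    expect_equal(res$df_total, rep(10, 30))
    expect_equal(res$s2_post, rep(0.5, 30))
    expect_true(all(res$p >= 0 & res$p <= 1))
})
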