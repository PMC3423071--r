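test_that("jittered-count moments reduce to the binomial case and hand sums", {
    m <- jitteredMoments(c(0.5, 0.5))
    expect_equal(m$mean, 1)
    expect_equal(m$variance, 0.5)
    m0 <- jitteredMoments(numeric(0))
    expect_equal(m0$mean, 0)
    expect_equal(m0$variance, 0)
    m2 <- jitteredMoments(c(0.2, 0.7))
    expect_equal(m2$mean, 0.9)
    expect_equal(m2$variance, 0.37)  # 0.2*0.8 + 0.7*0.3
    expect_error(jitteredMoments(c(0.5, 1.2)))
})

test_that("Z-score standardizes the observed count against the jitter null", {
    p <- rep(0.5, 16)
    expect_equal(zScore(8, p), 0)
    expect_equal(zScore(0, p), -sqrt(16))  # (0 - n/2)/sqrt(n/4) = -sqrt(n)
    expect_error(zScore(1, c(0, 1)), "variance")
})

test_that("JBSI hits 1 at perfect synchrony, -1 at the anti-synchronous extreme, 0 at chance", {
    params <- SynchronyParams(1, 2)
    ## isolated coincident spikes: p_i = 1/alpha = 0.5
    expect_equal(jbsiIndex(4, rep(0.5, 4), 4, params), 1)
    expect_equal(jbsiIndex(0, rep(0.5, 10), 10, params), -1)
    expect_equal(jbsiIndex(5, c(rep(0.5, 9), 0.5), 10, params), 0)
    expect_error(jbsiIndex(0, numeric(0), 0, params), "empty")
    ## beta switches at alpha = 2
    expect_equal(betaFactor(SynchronyParams(1, 2)), 2)
    expect_equal(betaFactor(SynchronyParams(1, 4)), 4 / 3)
    ## perfect synchrony through the full pipeline: JBSI = R_C = 1
    res <- analyzeSynchrony(perfectPair(10), params)
    expect_equal(jbsiValue(res), 1)
    expect_equal(coincidenceRate(res), 1)
})

test_that("exact Poisson-binomial recursion matches full enumeration and its analytic moments", {
    expect_equal(exactDistribution(c(0.5, 0.5)), c(0.25, 0.5, 0.25))
    expect_equal(exactDistribution(c(0.2, 0.7)), c(0.24, 0.62, 0.14))
    expect_equal(exactDistribution(1), c(0, 1))
    set.seed(31)
    for (n in c(1, 5, 8, 12)) {
        p <- runif(n)
        d <- exactDistribution(p)
        expect_lt(max(abs(d - brutePoissonBinomial(p))), 1e-12)
        expect_lt(abs(sum(d) - 1), 1e-12)
        k <- 0:n
        m <- jitteredMoments(p)
        expect_lt(abs(sum(k * d) - m$mean), 1e-9)
        expect_lt(abs(sum(k^2 * d) - sum(k * d)^2 - m$variance), 1e-9)
    }
})

test_that("exact and normal p-values agree for large n and are sensible at the mode", {
    set.seed(37)
    for (rep in 1:5) {
        p <- runif(120, 0.2, 0.8)
        nc <- round(sum(p) + rnorm(1, 0, sqrt(sum(p * (1 - p)))))
        nc <- max(0, min(length(p), nc))
        pe <- synchronyPValue(nc, p, mode = "exact")
        pn <- synchronyPValue(nc, p, mode = "normal")
        expect_lt(abs(pe - pn) / max(pe, pn), 0.10)
    }
    ## observed count at the mode of a symmetric null: p-value near 1
    expect_gt(synchronyPValue(8, rep(0.5, 16), mode = "exact"), 0.8)
    expect_error(synchronyPValue(1, rep(0.5, 10001), mode = "exact"),
                 "normal")
    ## one-sided tails
    expect_equal(synchronyPValue(16, rep(0.5, 16), mode = "exact",
                                 alternative = "greater"), 0.5^16)
})

test_that("Monte-Carlo surrogates reproduce the analytic mean, variance and distribution", {
    set.seed(41)
    pair <- randomSparsePair(40, 50, 1500, 0)
    params <- SynchronyParams(2, 4)
    p <- probabilityVector(pair, params)
    m <- jitteredMoments(p)
    counts <- monteCarloSurrogates(pair, params, 1e4, seed = 99)
    se_mean <- sqrt(m$variance / 1e4)
    expect_lt(abs(mean(counts) - m$mean), 3 * se_mean)
    ## variance within sampling error (chi-square spread ~ var*sqrt(2/n))
    expect_lt(abs(var(counts) - m$variance),
              4 * m$variance * sqrt(2 / 1e4))
    ## chi-square against the exact distribution, pooling sparse classes
    d <- exactDistribution(p)
    expd <- d * 1e4
    obs <- tabulate(counts + 1L, nbins = length(d))
    ord <- order(expd, decreasing = TRUE)
    keep <- ord[cumsum(expd[ord]) <= 1e4 - 5 & expd[ord] >= 5]
    pool <- setdiff(seq_along(d), keep)
    o <- c(obs[keep], sum(obs[pool]))
    e <- c(expd[keep], sum(expd[pool]))
    stat <- sum((o - e)^2 / e)
    expect_gt(stats::pchisq(stat, df = length(o) - 1, lower.tail = FALSE),
              0.01)
})

test_that("analysis is invariant under common time shift and time reversal", {
    set.seed(43)
    pair <- randomSparsePair(30, 40, 800, 0)
    params <- SynchronyParams(1.5, 3)
    res <- analyzeSynchrony(pair, params)
    ## common shift
    sh <- 37.5
    shift <- function(st, s, T) SpikeTrain(spikeTimes(st) + s,
                                           epochStart = s, epochEnd = T + s)
    pairS <- PairedRecording(shift(referenceTrain(pair), sh, 800),
                             shift(targetTrain(pair), sh, 800))
    resS <- analyzeSynchrony(pairS, params)
    expect_equal(jbsiValue(resS), jbsiValue(res), tolerance = 1e-12)
    expect_identical(coincidenceCount(resS), coincidenceCount(res))
    ## time reversal
    revT <- function(st, T) SpikeTrain(sort(T - spikeTimes(st)),
                                       epochEnd = T)
    pairR <- PairedRecording(revT(referenceTrain(pair), 800),
                             revT(targetTrain(pair), 800))
    resR <- analyzeSynchrony(pairR, params)
    expect_equal(jbsiValue(resR), jbsiValue(res), tolerance = 1e-9)
    expect_identical(coincidenceCount(resR), coincidenceCount(res))
})

test_that("degenerate and empty inputs are handled explicitly", {
    ## all p_i in {0, 1}: Z undefined, JBSI still reported
    far <- PairedRecording(SpikeTrain(100, epochEnd = 300),
                           SpikeTrain(250, epochEnd = 300))
    res <- analyzeSynchrony(far, SynchronyParams(1, 2))
    expect_true(is.na(zValue(res)))
    expect_equal(jbsiValue(res), 0)
    empty <- PairedRecording(SpikeTrain(numeric(0), epochEnd = 300),
                             SpikeTrain(250, epochEnd = 300))
    expect_error(analyzeSynchrony(empty, SynchronyParams(1, 2)), "empty")
})

test_that("JBSI stays within [-1, 1] for alpha <= 2 on random and simulated pairs", {
    set.seed(47)
    for (rep in 1:15) {
        pair <- randomSparsePair(sample(5:40, 1), sample(5:40, 1), 300, 0)
        res <- analyzeSynchrony(pair, SynchronyParams(runif(1, 0.3, 4)))
        expect_gte(jbsiValue(res), -1 - 1e-12)
        expect_lte(jbsiValue(res), 1 + 1e-12)
    }
})
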