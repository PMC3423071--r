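test_that("synchrony windows merge correctly, including exact abutment", {
    U <- mergeSynchronyWindows(c(10, 11), 0.25)
    expect_equal(unname(U), rbind(c(9.75, 10.25), c(10.75, 11.25)))
    ## overlapping windows fuse
    U2 <- mergeSynchronyWindows(c(10, 10.3), 0.25)
    expect_equal(unname(U2), rbind(c(9.75, 10.55)))
    ## windows meeting exactly at one point merge into one segment
    U3 <- mergeSynchronyWindows(c(10, 10.5), 0.25)
    expect_equal(unname(U3), rbind(c(9.75, 10.75)))
    expect_identical(nrow(mergeSynchronyWindows(numeric(0), 1)), 0L)
})

test_that("union segments are disjoint, sorted, and never longer than 2*tauS*n2", {
    set.seed(11)
    for (rep in 1:20) {
        t2 <- sort(runif(50, 0, 500))
        tauS <- runif(1, 0.5, 10)
        U <- mergeSynchronyWindows(t2, tauS)
        expect_true(all(U[, 2] > U[, 1]))
        if (nrow(U) > 1) {
            expect_true(all(diff(U[, 1]) > 0))
            expect_true(all(U[-1, 1] > U[-nrow(U), 2]))  # strict gaps
        }
        expect_lte(sum(U[, 2] - U[, 1]), 2 * tauS * length(t2) + 1e-9)
    }
})

test_that("coincidence counting matches the pairwise brute-force oracle", {
    p1 <- PairedRecording(SpikeTrain(10, epochEnd = 20),
                          SpikeTrain(10.4, epochEnd = 20))
    expect_identical(countCoincidences(p1, 0.5), 1L)
    p2 <- PairedRecording(SpikeTrain(10, epochEnd = 20),
                          SpikeTrain(11, epochEnd = 20))
    expect_identical(countCoincidences(p2, 0.5), 0L)
    ## each reference spike counted once even with overlapping windows
    p3 <- PairedRecording(SpikeTrain(c(10, 10.3), epochEnd = 20),
                          SpikeTrain(c(10.1, 10.2), epochEnd = 20))
    expect_identical(countCoincidences(p3, 0.5), 2L)
    ## empty target
    p4 <- PairedRecording(SpikeTrain(10, epochEnd = 20),
                          SpikeTrain(numeric(0), epochEnd = 20))
    expect_identical(countCoincidences(p4, 0.5), 0L)
    set.seed(7)
    for (rep in 1:20) {
        pair <- randomSparsePair(30, 40, 1000, 0)
        tauS <- runif(1, 0.5, 8)
        expect_identical(
            countCoincidences(pair, tauS),
            bruteCoincidences(spikeTimes(referenceTrain(pair)),
                              spikeTimes(targetTrain(pair)), tauS))
    }
})

test_that("jitter probability follows the isolated-window geometry", {
    tauS <- 1; tauJ <- 2
    U <- mergeSynchronyWindows(100, tauS)
    ## spike exactly on an isolated target spike: 2*tauS / (2*tauJ)
    expect_equal(jitterProbability(100, U, tauJ), 0.5)
    ## spike at |dt| = tauJ: overlap tauJ + tauS - |dt| = 1 over 4
    expect_equal(jitterProbability(102, U, tauJ), 0.25)
    ## farther than tauJ + tauS: zero
    expect_equal(jitterProbability(103.5, U, tauJ), 0)
    ## empty union
    expect_equal(jitterProbability(100, mergeSynchronyWindows(numeric(0), 1),
                                   tauJ), 0)
})

test_that("general probability algorithm equals the closed form on sparse targets", {
    set.seed(13)
    for (rep in 1:20) {
        tauS <- runif(1, 0.5, 3)
        tauJ <- tauS * runif(1, 1, 4)
        pair <- randomSparsePair(25, 20, 2000, minGap = 2 * tauS + 0.01)
        p <- probabilityVector(pair, SynchronyParams(tauS, tauJ))
        ref <- closedFormP(spikeTimes(referenceTrain(pair)),
                           spikeTimes(targetTrain(pair)), tauS, tauJ)
        expect_equal(p, ref, tolerance = 1e-12)
    }
})

test_that("probability vector is bounded, zero iff disjoint, and counts are consistent with the union", {
    ## single isolated coincident pair: p = tauS / tauJ
    pr <- PairedRecording(SpikeTrain(100, epochEnd = 200),
                          SpikeTrain(100.2, epochEnd = 200))
    expect_equal(probabilityVector(pr, SynchronyParams(1, 2)), 0.5)
    ## empty reference train gives empty vector
    pe <- PairedRecording(SpikeTrain(numeric(0), epochEnd = 200),
                          SpikeTrain(100, epochEnd = 200))
    expect_length(probabilityVector(pe, SynchronyParams(1, 2)), 0)
    set.seed(19)
    for (rep in 1:10) {
        pair <- randomSparsePair(40, 40, 500, 0)
        params <- SynchronyParams(runif(1, 0.5, 5))
        p <- probabilityVector(pair, params)
        expect_true(all(p >= 0 & p <= 1))
        ## p_i = 0 exactly when the jitter window misses every target window
        d <- vapply(spikeTimes(referenceTrain(pair)), function(x)
            min(abs(x - spikeTimes(targetTrain(pair)))), numeric(1))
        expect_identical(p == 0, d >= tauJ(params) + tauS(params))
        ## counting and union representations agree
        U <- mergeSynchronyWindows(targetTrain(pair), tauS(params))
        inU <- vapply(spikeTimes(referenceTrain(pair)), function(x)
            any(x >= U[, 1] & x <= U[, 2]), logical(1))
        expect_identical(countCoincidences(pair, tauS(params)),
                         as.integer(sum(inU)))
    }
})

test_that("Monte-Carlo jitter frequency converges to the computed p_i", {
    set.seed(23)
    t2 <- c(50, 53, 60, 80)
    tauS <- 1.5; tauJ <- 4
    U <- mergeSynchronyWindows(t2, tauS)
    for (t1 in c(51, 55.5, 79, 84.9)) {
        p <- jitterProbability(t1, U, tauJ)
        draws <- t1 + runif(1e5, -tauJ, tauJ)
        k <- findInterval(draws, U[, 1])
        hits <- mean(k >= 1 & draws <= U[pmax(k, 1), 2])
        ## binomial 99% interval at 1e5 draws
        half <- 2.576 * sqrt(max(p * (1 - p), 1e-6) / 1e5)
        expect_lt(abs(hits - p), half + 1e-3)
    }
})
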