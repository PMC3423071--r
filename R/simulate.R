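## Paired spike-train simulator: Poisson firing by per-bin Bernoulli draws
## with a refractory period, optional sinusoidal rate co-modulation, and
## controlled coincidence injection.

#' Rectified-sinusoid co-modulated firing rate
#'
#' rate(t) = baseRate * c(M) * |sin(2*pi*t / 1000)|^M, the underlying
#' sinusoid having a 1 s period so the rectified modulation repeats every
#' 0.5 s. The constant c(M) normalizes the time-average of the modulation
#' factor to 1, keeping the expected total spike count unchanged across M.
#' M = 0 returns the constant base rate.
#'
#' @param t time in ms (vectorized).
#' @param baseRate mean firing rate in Hz.
#' @param M modulation exponent (>= 0).
#' @return numeric rate(s) in Hz.
#' @export
comodulatedRate <- function(t, baseRate, M) {
    stopifnot(M >= 0)
    if (M == 0) return(rep(baseRate, length(t)))
    baseRate * abs(sin(2 * pi * t / 1000))^M / .sinMoment(M)
}

## E|sin|^M over one period, by quadrature; cached per M
.sinMomentCache <- new.env(parent = emptyenv())
.sinMoment <- function(M) {
    key <- format(M, digits = 15)
    if (is.null(.sinMomentCache[[key]]))
        .sinMomentCache[[key]] <- stats::integrate(
            function(u) abs(sin(pi * u))^M, 0, 1,
            rel.tol = 1e-10)$value
    .sinMomentCache[[key]]
}

#' Epoch length giving a requested expected spike count
#'
#' With per-bin firing probability p = rate * bin / 1000 and a refractory
#' period blocking `refractory/bin` bins after each spike, the generator
#' emits p / (1 + (refractory/bin) * p) spikes per bin (a renewal-rate
#' correction below the nominal rate). This returns the epoch length (ms)
#' at which the expected count equals `n`, used to size simulations "about
#' n spikes" long.
#'
#' @param rate mean firing rate in Hz.
#' @param n desired expected spike count (default 1000).
#' @param refractory refractory period in ms.
#' @param bin bin width in ms.
#' @return epoch length in ms, rounded to an integer.
#' @examples
#' epochForSpikeCount(45)  # ~24 s for ~1000 spikes at 45 Hz
#' @export
epochForSpikeCount <- function(rate, n = 1000, refractory = 2, bin = 1) {
    stopifnot(rate > 0, n > 0)
    p <- rate * bin / 1000
    round(n * (1 + (refractory / bin) * p) / p * bin)
}

#' Generate a Poisson spike train with refractory period
#'
#' Per 1 ms (or `bin` ms) time bin, a spike is fired when a uniform draw
#' falls below rate(t) * bin (rate in spikes/ms); the spike time is then
#' placed uniformly within the bin. After a spike, the bins covering the
#' next `refractory` ms are skipped, so all interspike intervals exceed the
#' refractory period. Draw order: one uniform per bin first, then one
#' uniform per accepted spike for its within-bin placement.
#'
#' @param rate mean firing rate in Hz; `rate * bin / 1000` must be < 1.
#' @param T epoch length in ms.
#' @param refractory refractory period in ms (default 2).
#' @param bin bin width in ms (default 1).
#' @param rateModulator optional function of time (ms) returning the
#'   instantaneous rate in Hz, overriding `rate`; evaluated at bin
#'   midpoints.
#' @param seed optional integer seed.
#' @return A [SpikeTrain-class] on \[0, T\].
#' @export
generatePoissonTrain <- function(rate, T, refractory = 2, bin = 1,
                                 rateModulator = NULL, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    nb <- ceiling(T / bin)
    if (is.null(rateModulator)) {
        if (rate * bin / 1000 >= 1)
            stop("per-bin firing probability rate*bin must be < 1")
        pr <- rep(rate * bin / 1000, nb)
    } else {
        pr <- rateModulator((seq_len(nb) - 0.5) * bin) * bin / 1000
        if (any(pr >= 1))
            stop("per-bin firing probability rate*bin must be < 1")
    }
    fired <- which(stats::runif(nb) < pr)
    ## enforce refractory: a spike in bin b blocks all bins within
    ## `refractory` ms after it
    skip <- refractory / bin
    keep <- integer(length(fired))
    nk <- 0L
    last <- -Inf
    for (b in fired) {
        if (b - last > skip) {
            nk <- nk + 1L
            keep[nk] <- b
            last <- b
        }
    }
    keep <- keep[seq_len(nk)]
    times <- (keep - 1L + stats::runif(nk)) * bin
    new("SpikeTrain", times = times, epochStart = 0, epochEnd = as.numeric(T))
}

#' Inject controlled coincidences into a spike-train pair
#'
#' Each reference spike is selected independently with probability `D` and
#' moved to a time drawn uniformly within +/-C of the earliest target spike
#' at or after its original time (selected spikes with no later target
#' spike stay put). The shifted train is re-sorted and any of its spikes
#' violating the refractory period is removed (the later spike of an
#' offending pair, preserving the injected coincidence). Shifted spikes
#' landing outside the epoch are dropped.
#'
#' @param pair a [PairedRecording-class]; the reference train receives the
#'   shifts.
#' @param D selection probability per reference spike, in \[0, 1\].
#' @param C coincidence precision in ms (>= 0).
#' @param refractory refractory period in ms.
#' @param seed optional integer seed.
#' @return A [PairedRecording-class] with the modified reference train.
#' @export
injectCoincidences <- function(pair, D, C, refractory = 2, seed = NULL) {
    stopifnot(is(pair, "PairedRecording"), D >= 0, D <= 1, C >= 0)
    if (!is.null(seed)) set.seed(seed)
    t1 <- spikeTimes(pair@reference)
    t2 <- spikeTimes(pair@target)
    n1 <- length(t1)
    if (D == 0 || n1 == 0L || length(t2) == 0L) return(pair)
    sel <- stats::runif(n1) < D
    ## earliest target spike at or after each reference spike
    nxt <- findInterval(t1, t2, left.open = TRUE) + 1L
    move <- sel & nxt <= length(t2)
    t1[move] <- t2[nxt[move]] + stats::runif(sum(move), -C, C)
    t1 <- sort(t1)
    eS <- pair@reference@epochStart
    eE <- pair@reference@epochEnd
    t1 <- t1[t1 >= eS & t1 <= eE]
    ## remove later spike of any pair violating the refractory period
    if (length(t1) > 1L && refractory > 0) {
        keep <- logical(length(t1))
        last <- -Inf
        for (i in seq_along(t1)) {
            if (t1[i] - last >= refractory) {
                keep[i] <- TRUE
                last <- t1[i]
            }
        }
        t1 <- t1[keep]
    }
    PairedRecording(
        reference = new("SpikeTrain", times = t1, epochStart = eS,
                        epochEnd = eE),
        target = pair@target)
}

#' Simulate a pair of spike trains with controlled synchrony
#'
#' Generates two independent Poisson trains with refractory period (sharing
#' the same rectified-sinusoid rate modulator when M > 0), then injects
#' coincidences at rate D and precision C into the first (reference) train
#' and re-enforces its refractory period. Draw order is fixed (train 1
#' bins and placements, train 2 bins and placements, selection mask,
#' displacements) so a given seed is bit-reproducible. Because refractory
#' re-enforcement removes some shifted spikes, final counts of the two
#' trains typically differ by 5-10 percent even at equal rates.
#'
#' @param config a [SimConfig-class].
#' @return A [PairedRecording-class]; the first (shifted) train is the
#'   reference.
#' @examples
#' pair <- simulatePair(SimConfig(rate1 = 45, rate2 = 45, T = 10000,
#'                                D = 0.2, C = 1, seed = 7))
#' pair
#' @export
simulatePair <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    if (!is.na(config@seed)) set.seed(config@seed)
    mod1 <- mod2 <- NULL
    if (config@M > 0) {
        mod1 <- function(t) comodulatedRate(t, config@rate1, config@M)
        mod2 <- function(t) comodulatedRate(t, config@rate2, config@M)
    }
    ref <- generatePoissonTrain(config@rate1, config@T,
                                refractory = config@refractory,
                                bin = config@bin, rateModulator = mod1)
    tgt <- generatePoissonTrain(config@rate2, config@T,
                                refractory = config@refractory,
                                bin = config@bin, rateModulator = mod2)
    pair <- PairedRecording(reference = ref, target = tgt)
    injectCoincidences(pair, config@D, config@C,
                       refractory = config@refractory)
}
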