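#' @import methods
NULL

#' SpikeTrain: a sorted point process of spike times
#'
#' An S4 container for a single neuron's spike train: strictly increasing
#' spike occurrence times (milliseconds) together with the recording-epoch
#' bounds. The epoch duration enters all chance-coincidence expectations, so
#' it is carried explicitly rather than inferred downstream.
#'
#' @slot times numeric, strictly increasing spike times in ms.
#' @slot epochStart numeric(1), start of the recording epoch (ms).
#' @slot epochEnd numeric(1), end of the recording epoch (ms);
#'   `epochStart <= times[1]` and `times[n] <= epochEnd`.
#'
#' @examples
#' st <- SpikeTrain(c(10, 25.5, 40), epochEnd = 100)
#' nSpikes(st)
#' firingRate(st)
#' @export
setClass("SpikeTrain",
    representation(times = "numeric", epochStart = "numeric",
                   epochEnd = "numeric"))

setValidity("SpikeTrain", function(object) {
    t <- object@times
    if (anyNA(t) || any(!is.finite(t)))
        return("spike times must be finite and non-missing")
    if (is.unsorted(t, strictly = TRUE))
        return("spike times must be strictly increasing (no duplicates)")
    if (length(object@epochStart) != 1L || length(object@epochEnd) != 1L)
        return("epoch bounds must be scalar")
    if (object@epochEnd <= object@epochStart)
        return("epochEnd must exceed epochStart")
    if (length(t) > 0L) {
        if (t[1L] < object@epochStart)
            return("first spike precedes epochStart")
        if (t[length(t)] > object@epochEnd)
            return("last spike exceeds epochEnd")
    }
    TRUE
})

#' Construct a SpikeTrain
#'
#' Builds a [SpikeTrain-class] from raw spike times. Unsorted input is sorted
#' with a warning; duplicate timestamps are collapsed with a warning (a
#' neuron cannot fire twice at one instant). When `epochEnd` is not supplied
#' it defaults to the largest spike time rounded up to an integer
#' millisecond.
#'
#' @param times numeric vector of spike times in ms.
#' @param epochStart start of the recording epoch (ms), default 0.
#' @param epochEnd end of the recording epoch (ms); default
#'   `ceiling(max(times))`.
#' @return A [SpikeTrain-class] object.
#' @export
SpikeTrain <- function(times = numeric(0), epochStart = 0, epochEnd = NULL) {
    times <- as.numeric(times)
    if (anyNA(times) || any(!is.finite(times)))
        stop("spike times must be finite and non-missing")
    if (is.unsorted(times)) {
        warning("spike times were not sorted; sorting")
        times <- sort(times)
    }
    if (anyDuplicated(times)) {
        warning("duplicate spike times collapsed")
        times <- unique(times)
    }
    if (is.null(epochEnd))
        epochEnd <- if (length(times)) max(ceiling(max(times)), epochStart + 1)
                    else epochStart + 1
    new("SpikeTrain", times = times, epochStart = as.numeric(epochStart),
        epochEnd = as.numeric(epochEnd))
}

#' PairedRecording: two simultaneously recorded spike trains
#'
#' Holds a reference train (the one that is virtually jittered; by
#' convention the train with fewer spikes) and a target train sharing the
#' same recording epoch. Use [assignRoles()] to build one with the
#' fewer-spikes-is-reference rule applied.
#'
#' @slot reference a [SpikeTrain-class]; the jittered train (n1 spikes).
#' @slot target a [SpikeTrain-class]; the fixed train (n2 spikes).
#' @export
setClass("PairedRecording",
    representation(reference = "SpikeTrain", target = "SpikeTrain"))

setValidity("PairedRecording", function(object) {
    r <- object@reference; tg <- object@target
    if (r@epochStart != tg@epochStart || r@epochEnd != tg@epochEnd)
        return("reference and target must share identical epoch bounds")
    TRUE
})

#' Construct a PairedRecording
#'
#' Direct constructor keeping `reference` and `target` as given (no role
#' swapping); see [assignRoles()] for the fewer-spikes-is-reference rule.
#'
#' @param reference,target [SpikeTrain-class] objects sharing one epoch.
#' @return A [PairedRecording-class] object.
#' @export
PairedRecording <- function(reference, target) {
    new("PairedRecording", reference = reference, target = target)
}

#' SynchronyParams: synchrony span, jitter span and derived scaling
#'
#' The two analysis time scales of the jitter method: the synchrony span
#' tauS (half-width of the coincidence window around each target spike) and
#' the jitter span tauJ (half-width of the uniform virtual displacement of
#' each reference spike). The ratio alpha = tauJ/tauS determines the index
#' scaling beta: beta = 2 when alpha <= 2 and alpha/(alpha - 1) otherwise,
#' which pins perfect synchrony at index 1.
#'
#' @slot tauS numeric(1), synchrony span in ms, > 0.
#' @slot tauJ numeric(1), jitter span in ms, >= tauS.
#' @export
setClass("SynchronyParams",
    representation(tauS = "numeric", tauJ = "numeric"))

setValidity("SynchronyParams", function(object) {
    if (length(object@tauS) != 1L || length(object@tauJ) != 1L)
        return("tauS and tauJ must be scalar")
    if (!is.finite(object@tauS) || object@tauS <= 0)
        return("tauS must be a positive finite number of ms")
    if (!is.finite(object@tauJ) || object@tauJ < object@tauS)
        return("tauJ must be >= tauS: a jitter smaller than the synchrony span cannot separate chance from real coincidences")
    TRUE
})

#' Construct SynchronyParams
#'
#' @param tauS synchrony span in ms (> 0).
#' @param tauJ jitter span in ms; defaults to `2 * tauS` (alpha = 2, the
#'   ratio giving the JBSI its full \[-1, 1\] dynamic range).
#' @return A [SynchronyParams-class] object.
#' @examples
#' SynchronyParams(1)        # tauS = 1 ms, tauJ = 2 ms
#' SynchronyParams(1, 4)     # alpha = 4, beta = 4/3
#' @export
SynchronyParams <- function(tauS, tauJ = 2 * tauS) {
    new("SynchronyParams", tauS = as.numeric(tauS), tauJ = as.numeric(tauJ))
}

#' SynchronyResult: full output of a jitter-based synchrony analysis
#'
#' Produced by [analyzeSynchrony()]. Holds the observed coincidence count
#' and rate, the per-spike jitter-synchrony probability vector, the analytic
#' mean and variance of the jittered count, the Z-score, the p-value and the
#' JBSI, together with the parameters and train sizes needed to reproduce
#' them.
#'
#' @slot nC integer(1), observed coincidence count.
#' @slot p numeric, per-reference-spike probability of being synchronous
#'   after a uniform jitter (length n1).
#' @slot expectedJittered numeric(1), sum(p).
#' @slot variance numeric(1), sum(p * (1 - p)).
#' @slot z numeric(1), Z-score (NA when variance is 0).
#' @slot pValue numeric(1), p-value (NA when variance is 0 in normal mode).
#' @slot jbsi numeric(1), the Jitter-Based Synchrony Index.
#' @slot params the [SynchronyParams-class] used.
#' @slot n1,n2 integer(1), spike counts of reference and target trains.
#' @slot T numeric(1), epoch duration in ms.
#' @export
setClass("SynchronyResult",
    representation(nC = "integer", p = "numeric",
                   expectedJittered = "numeric", variance = "numeric",
                   z = "numeric", pValue = "numeric", jbsi = "numeric",
                   params = "SynchronyParams",
                   n1 = "integer", n2 = "integer", T = "numeric"))

#' SimConfig: parameters of the paired spike-train simulator
#'
#' Parameter set for [simulatePair()]: two Poisson trains generated by
#' per-bin Bernoulli draws with a refractory period, controlled coincidence
#' injection (each reference spike is moved, with probability D, to within
#' +/-C of the next target spike), and optional sinusoidal rate
#' co-modulation of exponent M shared by the two neurons.
#'
#' @slot rate1,rate2 numeric(1), mean firing rates in Hz.
#' @slot T numeric(1), epoch length in ms.
#' @slot D numeric(1) in \[0, 1\], coincidence injection probability per
#'   reference spike.
#' @slot C numeric(1) >= 0, coincidence precision in ms.
#' @slot M numeric(1) >= 0, co-modulation exponent (0 = none).
#' @slot refractory numeric(1) >= 0, refractory period in ms (default 2).
#' @slot bin numeric(1), simulation bin width in ms (default 1).
#' @slot seed numeric(1), PRNG seed (NA = leave the PRNG state alone).
#' @export
setClass("SimConfig",
    representation(rate1 = "numeric", rate2 = "numeric", T = "numeric",
                   D = "numeric", C = "numeric", M = "numeric",
                   refractory = "numeric", bin = "numeric", seed = "numeric"))

setValidity("SimConfig", function(object) {
    if (object@rate1 < 0 || object@rate2 < 0) return("rates must be >= 0")
    if (object@T <= 0) return("epoch length T must be positive")
    if (object@D < 0 || object@D > 1) return("D must lie in [0, 1]")
    if (object@C < 0) return("C must be >= 0")
    if (object@M < 0) return("M must be >= 0")
    if (object@refractory < 0) return("refractory must be >= 0")
    if (object@bin <= 0) return("bin must be positive")
    if (max(object@rate1, object@rate2) * object@bin / 1000 >= 1)
        return("per-bin firing probability rate*bin must be < 1")
    TRUE
})

#' Construct a SimConfig
#'
#' @param rate1,rate2 mean firing rates in Hz.
#' @param T epoch length in ms.
#' @param D coincidence injection probability per reference spike, in
#'   \[0, 1\].
#' @param C coincidence precision in ms.
#' @param M co-modulation exponent (0 disables modulation).
#' @param refractory refractory period in ms.
#' @param bin simulation bin width in ms.
#' @param seed PRNG seed, or NA to use the current PRNG state.
#' @return A [SimConfig-class] object.
#' @export
SimConfig <- function(rate1 = 45, rate2 = 45, T = epochForSpikeCount(rate1),
                      D = 0, C = 1,
                      M = 0, refractory = 2, bin = 1, seed = NA_real_) {
    ## Class named explicitly: a slot called "C" would otherwise partially
    ## match new()'s Class argument
    new(Class = "SimConfig",
        rate1 = as.numeric(rate1), rate2 = as.numeric(rate2),
        T = as.numeric(T), D = as.numeric(D), C = as.numeric(C),
        M = as.numeric(M), refractory = as.numeric(refractory),
        bin = as.numeric(bin), seed = as.numeric(seed))
}

#' SweepResult: jitter-span sweep over a geometric grid
#'
#' Produced by [sweepPrecision()]. Per grid point the Z-score and JBSI of
#' every supplied pair, from which run-averaged curves and standard errors
#' are derived; input to [zThresholdCrossing()] and [jbsiCutoff()].
#'
#' @slot tauSGrid,tauJGrid numeric, strictly increasing grids in ms with
#'   `tauJGrid = alpha * tauSGrid`.
#' @slot zValues,jbsiValues numeric matrices (grid points x pairs).
#' @slot alpha numeric(1), the fixed tauJ/tauS ratio of the sweep.
#' @export
setClass("SweepResult",
    representation(tauSGrid = "numeric", tauJGrid = "numeric",
                   zValues = "matrix", jbsiValues = "matrix",
                   alpha = "numeric"))

setValidity("SweepResult", function(object) {
    g <- object@tauJGrid
    if (is.unsorted(g, strictly = TRUE))
        return("tauJGrid must be strictly increasing")
    if (length(object@tauSGrid) != length(g))
        return("tauSGrid and tauJGrid lengths differ")
    if (nrow(object@zValues) != length(g) ||
        nrow(object@jbsiValues) != length(g))
        return("curve matrices must have one row per grid point")
    TRUE
})
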