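## The jitter-based synchrony statistics: analytic moments of the jittered
## coincidence count, Z-score, exact Poisson-binomial distribution, p-values
## and the JBSI itself.

#' Mean and variance of the jittered coincidence count
#'
#' The coincidence count after an independent uniform jitter of every
#' reference spike is a sum of independent Bernoulli variables with success
#' probabilities `p`, so its mean is `sum(p)` and its variance
#' `sum(p * (1 - p))` (the binomial formulas when all p_i are equal).
#'
#' @param p numeric vector of per-spike probabilities in \[0, 1\].
#' @return list with elements `mean` and `variance`.
#' @examples
#' jitteredMoments(c(0.5, 0.5))  # binomial n = 2, p = 1/2: mean 1, var 0.5
#' @export
jitteredMoments <- function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    list(mean = sum(p), variance = sum(p * (1 - p)))
}

#' Z-score of the observed coincidence count under the jitter null
#'
#' Standardized distance of the observed count from the analytic jitter-null
#' mean: positive for excess synchrony, negative for less-than-expected
#' synchrony.
#'
#' @param nC observed coincidence count.
#' @param p probability vector from [probabilityVector()].
#' @return numeric Z-score.
#' @export
zScore <- function(nC, p) {
    m <- jitteredMoments(p)
    if (m$variance <= 0)
        stop("jitter-null variance is zero (all p_i are 0 or 1); Z undefined")
    (nC - m$mean) / sqrt(m$variance)
}

#' The Jitter-Based Synchrony Index
#'
#' JBSI = beta * (N_C - sum(p)) / n1, where beta (from `params`) scales the
#' index so that perfect synchrony yields 1. With alpha = tauJ/tauS <= 2 the
#' index is bounded in \[-1, 1\]; 0 indicates chance-level synchrony and
#' negative values less-than-expected synchrony (not anti-phase firing).
#'
#' @param nC observed coincidence count.
#' @param p probability vector (length n1).
#' @param n1 number of reference spikes (>= 1).
#' @param params a [SynchronyParams-class].
#' @return numeric index value.
#' @export
jbsiIndex <- function(nC, p, n1, params) {
    if (n1 < 1L) stop("JBSI undefined for an empty reference train")
    if (length(p) != n1)
        stop("probability vector length must equal n1")
    betaFactor(params) * (nC - sum(p)) / n1
}

#' Exact jitter-null distribution of the coincidence count
#'
#' Computes the Poisson-binomial probability mass function P(N), N =
#' 0..n1, of a sum of independent Bernoulli trials with success
#' probabilities `p`, by the row recursion P_m(N) = p_m P_{m-1}(N-1) +
#' (1-p_m) P_{m-1}(N). Only the previous row is kept (O(n1^2) time, O(n1)
#' memory).
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @return numeric vector of length `length(p) + 1`, summing to 1; element
#'   N+1 is P(count = N).
#' @examples
#' exactDistribution(c(0.5, 0.5))  # 0.25 0.50 0.25
#' @export
exactDistribution <- function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    P <- 1
    for (pi in p)
        P <- c(P * (1 - pi), 0) + c(0, P * pi)
    P
}

#' p-value of the observed coincidence count
#'
#' Two-tailed by default. In `"normal"` mode the jitter-null distribution is
#' approximated by a normal with the analytic mean and variance (the
#' Poisson-binomial converges rapidly to normal); in `"exact"` mode the
#' smaller one-sided tail mass of the exact distribution at `nC` (inclusive)
#' is doubled and capped at 1. Exact mode refuses reference trains larger
#' than `maxExact` spikes; use normal mode there.
#'
#' @param nC observed coincidence count.
#' @param p probability vector.
#' @param mode `"normal"` or `"exact"`.
#' @param alternative `"two.sided"` (default), `"greater"` (excess
#'   synchrony) or `"less"`.
#' @param maxExact largest n1 accepted in exact mode (default 1e4).
#' @return numeric p-value in \[0, 1\].
#' @export
synchronyPValue <- function(nC, p, mode = c("normal", "exact"),
                            alternative = c("two.sided", "greater", "less"),
                            maxExact = 1e4) {
    mode <- match.arg(mode)
    alternative <- match.arg(alternative)
    if (mode == "normal") {
        z <- zScore(nC, p)
        switch(alternative,
               two.sided = 2 * stats::pnorm(-abs(z)),
               greater = stats::pnorm(z, lower.tail = FALSE),
               less = stats::pnorm(z))
    } else {
        if (length(p) > maxExact)
            stop(sprintf(
                "exact mode limited to n1 <= %d; use mode = \"normal\"",
                maxExact))
        d <- exactDistribution(p)
        lower <- sum(d[seq_len(nC + 1L)])
        upper <- sum(d[(nC + 1L):length(d)])
        switch(alternative,
               two.sided = min(1, 2 * min(lower, upper)),
               greater = upper,
               less = lower)
    }
}

#' Full jitter-based synchrony analysis of a spike-train pair
#'
#' Counts coincidences at `tauS`, computes the per-spike jitter-synchrony
#' probabilities at `tauJ`, and from them the analytic jitter-null mean and
#' variance, the Z-score, the p-value and the JBSI. If every p_i is 0 or 1
#' the null distribution is degenerate: Z and the p-value are returned as
#' NA while the JBSI is still defined.
#'
#' @param pair a [PairedRecording-class]; the reference train is the one
#'   that is (virtually) jittered.
#' @param params a [SynchronyParams-class].
#' @param pMode `"normal"` (default) or `"exact"` p-value computation.
#' @param alternative tail convention, see [synchronyPValue()].
#' @return A [SynchronyResult-class].
#' @examples
#' set.seed(1)
#' pair <- simulatePair(SimConfig(rate1 = 45, rate2 = 45, T = 5000,
#'                                D = 0.4, C = 1))
#' analyzeSynchrony(pair, SynchronyParams(1, 2))
#' @export
analyzeSynchrony <- function(pair, params = SynchronyParams(1, 2),
                             pMode = c("normal", "exact"),
                             alternative = c("two.sided", "greater",
                                             "less")) {
    stopifnot(is(pair, "PairedRecording"), is(params, "SynchronyParams"))
    pMode <- match.arg(pMode)
    alternative <- match.arg(alternative)
    n1 <- nSpikes(pair@reference)
    n2 <- nSpikes(pair@target)
    if (n1 == 0L) stop("reference train is empty; synchrony undefined")
    nC <- countCoincidences(pair, params@tauS)
    p <- probabilityVector(pair, params)
    m <- jitteredMoments(p)
    degenerate <- m$variance <= 0
    z <- if (degenerate) NA_real_ else (nC - m$mean) / sqrt(m$variance)
    pv <- if (degenerate && pMode == "normal") NA_real_
          else if (degenerate)
              synchronyPValue(nC, p, mode = "exact",
                              alternative = alternative)
          else synchronyPValue(nC, p, mode = pMode,
                               alternative = alternative)
    new("SynchronyResult",
        nC = as.integer(nC), p = p,
        expectedJittered = m$mean, variance = m$variance,
        z = z, pValue = pv,
        jbsi = jbsiIndex(nC, p, n1, params),
        params = params,
        n1 = as.integer(n1), n2 = as.integer(n2),
        T = epochDuration(pair))
}

#' Monte-Carlo jitter surrogates (validation oracle)
#'
#' Generates surrogate coincidence counts by explicitly jittering every
#' reference spike uniformly in \[-tauJ, +tauJ\] and recounting coincidences
#' against the untouched target train. The production statistics are
#' analytic; this sampler exists to validate them.
#'
#' @param pair a [PairedRecording-class].
#' @param params a [SynchronyParams-class].
#' @param nSurrogates number of independent surrogate realizations (>= 1).
#' @param seed optional integer seed.
#' @return integer vector of surrogate coincidence counts.
#' @export
monteCarloSurrogates <- function(pair, params, nSurrogates, seed = NULL) {
    stopifnot(is(pair, "PairedRecording"), is(params, "SynchronyParams"),
              nSurrogates >= 1)
    if (!is.null(seed)) set.seed(seed)
    t1 <- spikeTimes(pair@reference)
    n1 <- length(t1)
    U <- mergeSynchronyWindows(pair@target, params@tauS)
    counts <- integer(nSurrogates)
    for (s in seq_len(nSurrogates)) {
        jit <- t1 + stats::runif(n1, -params@tauJ, params@tauJ)
        counts[s] <- sum(.inUnion(jit, U))
    }
    counts
}

#' Serialize a SynchronyResult to JSON
#'
#' Emits the flat record \{n1, n2, T_ms, tau_s_ms, tau_j_ms, n_c, r_c,
#' expected, variance, z, p_value, jbsi\} with numbers at 12 significant
#' digits, so identical analyses serialize byte-identically.
#'
#' @param result a [SynchronyResult-class].
#' @return a JSON string (class `json`).
#' @export
resultToJSON <- function(result) {
    stopifnot(is(result, "SynchronyResult"))
    rec <- list(
        n1 = result@n1, n2 = result@n2,
        T_ms = signif(result@T, 12),
        tau_s_ms = signif(result@params@tauS, 12),
        tau_j_ms = signif(result@params@tauJ, 12),
        n_c = result@nC,
        r_c = signif(result@nC / result@n1, 12),
        expected = signif(result@expectedJittered, 12),
        variance = signif(result@variance, 12),
        z = if (is.na(result@z)) NULL else signif(result@z, 12),
        p_value = if (is.na(result@pValue)) NULL
                  else signif(result@pValue, 12),
        jbsi = signif(result@jbsi, 12))
    jsonlite::toJSON(rec[!vapply(rec, is.null, logical(1))],
                     auto_unbox = TRUE, digits = NA)
}
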