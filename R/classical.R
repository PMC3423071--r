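## Cross-correlogram and the classical synchrony indices the JBSI is
## compared against: expected chance count under stationary Poisson firing,
## ECI, CCC, their corrected forms, and the JSSI.

#' Expected chance coincidence count under stationary Poisson firing
#'
#' 2 * tauS * n1 * n2 / T: the mean coincidence count for two independent
#' stationary Poisson trains. All quantities in a single time unit (ms).
#'
#' @param n1,n2 spike counts of the two trains.
#' @param T epoch duration in ms (> 0).
#' @param tauS synchrony span in ms.
#' @return numeric expected count.
#' @examples
#' expectedChanceCount(10000, 10000, 250000, 0.5)  # 400
#' @export
expectedChanceCount <- function(n1, n2, T, tauS) {
    stopifnot(T > 0)
    2 * tauS * n1 * n2 / T
}

#' Cross-correlation histogram of two spike trains
#'
#' Histogram of all pairwise lags (target time minus reference time) within
#' \[-maxLag, +maxLag\], with the central bin symmetric about lag 0, plus
#' counts normalized by the number of reference spikes. With `binWidth =
#' 2 * tauS` the central normalized height equals the coincidence rate R_C
#' (up to reference spikes coincident only across a bin edge).
#'
#' @param pair a [PairedRecording-class].
#' @param binWidth bin width in ms (> 0), default 2.
#' @param maxLag maximal absolute lag in ms, default 50.
#' @return list with `binWidth`, `edges`, `centers`, `counts`,
#'   `normalized`.
#' @export
computeCCG <- function(pair, binWidth = 2, maxLag = 50) {
    stopifnot(is(pair, "PairedRecording"), binWidth > 0, maxLag >= binWidth / 2)
    t1 <- spikeTimes(pair@reference)
    t2 <- spikeTimes(pair@target)
    nHalf <- floor((maxLag - binWidth / 2) / binWidth)
    edges <- seq(-(nHalf + 0.5) * binWidth, (nHalf + 0.5) * binWidth,
                 by = binWidth)
    nb <- length(edges) - 1L
    counts <- integer(nb)
    if (length(t1) && length(t2)) {
        lo <- findInterval(t1 + edges[1L], t2, left.open = TRUE) + 1L
        hi <- findInterval(t1 + edges[nb + 1L], t2)
        lags <- unlist(lapply(which(hi >= lo), function(i)
            t2[lo[i]:hi[i]] - t1[i]), use.names = FALSE)
        if (length(lags)) {
            b <- findInterval(lags, edges, rightmost.closed = TRUE)
            b <- b[b >= 1L & b <= nb]
            counts <- tabulate(b, nbins = nb)
        }
    }
    n1 <- max(length(t1), 1L)
    list(binWidth = binWidth, edges = edges,
         centers = (edges[-1L] + edges[-(nb + 1L)]) / 2,
         counts = counts, normalized = counts / n1)
}

#' Excess Coincidence Index (ECI)
#'
#' (N_C - expected) / n1: the excess coincidence count per reference spike.
#' Sensitive to the overall firing rate; see [eciCor()].
#'
#' @param nC observed coincidence count.
#' @param expected expected chance count, e.g. [expectedChanceCount()].
#' @param n1 number of reference spikes (>= 1).
#' @return numeric index.
#' @export
eci <- function(nC, expected, n1) {
    stopifnot(n1 >= 1)
    (nC - expected) / n1
}

#' Corrected Excess Coincidence Index (ECIcor)
#'
#' (N_C - expected) / (n1 - expected). The correction removes the overlap
#' between chance and true coincidences (which are not mutually exclusive
#' sets), making the index rate-independent and equal to 1 at perfect
#' synchrony.
#'
#' @inheritParams eci
#' @return numeric index.
#' @export
eciCor <- function(nC, expected, n1) {
    if (expected >= n1)
        stop("ECIcor undefined: expected count >= n1")
    (nC - expected) / (n1 - expected)
}

#' Cross-correlation coefficient (CCC)
#'
#' The Z-score of the observed coincidence count under a hypergeometric
#' null (n1 and n2 spikes thrown independently into K = T/(2*tauS) bins),
#' normalized by sqrt(K - 1):
#' (N_C - n1*n2/K) / sqrt(n1*n2*(1 - n1/K)*(1 - n2/K)).
#'
#' @param nC observed coincidence count.
#' @param n1,n2 spike counts.
#' @param K number of bins, K = round(T / (2 * tauS)); must exceed n2.
#' @return numeric index.
#' @export
ccc <- function(nC, n1, n2, K) {
    if (K <= max(n1, n2))
        stop("CCC undefined: bin count K must exceed both spike counts")
    (nC - n1 * n2 / K) / sqrt(n1 * n2 * (1 - n1 / K) * (1 - n2 / K))
}

#' Maximum attainable CCC
#'
#' The CCC at the highest possible coincidence count N_C = n1:
#' sqrt((K/n2 - 1) / (K/n1 - 1)). Equals 1 only when n1 = n2, which is why
#' the raw CCC penalizes firing-rate differentials.
#'
#' @inheritParams ccc
#' @return numeric in (0, 1\].
#' @export
cccMax <- function(n1, n2, K) {
    if (K <= max(n1, n2))
        stop("CCCmax undefined: bin count K must exceed both spike counts")
    sqrt((K / n2 - 1) / (K / n1 - 1))
}

#' Corrected CCC
#'
#' ccc / cccMax; algebraically identical to [eciCor()] with expected =
#' n1*n2/K.
#'
#' @inheritParams ccc
#' @return numeric index.
#' @export
cccCor <- function(nC, n1, n2, K) {
    ccc(nC, n1, n2, K) / cccMax(n1, n2, K)
}

#' Jitter-Sensitive Synchrony Index (JSSI)
#'
#' Z / sqrt((alpha - 1) * n1), the jitter Z-score normalized by train
#' length. Included for comparison with earlier work; the JSSI retains a
#' negative dependence on the overall firing rate, so the JBSI is
#' preferable.
#'
#' @param z jitter-null Z-score, see [zScore()].
#' @param n1 number of reference spikes.
#' @param params a [SynchronyParams-class] with alpha > 1.
#' @return numeric index.
#' @export
jssi <- function(z, n1, params) {
    a <- alphaRatio(params)
    if (a <= 1) stop("JSSI undefined for alpha = tauJ/tauS <= 1")
    z / sqrt((a - 1) * n1)
}

#' All synchrony indices of a pair, side by side
#'
#' Computes the observed coincidence count at `tauS` and from it the JBSI
#' (with Z-score and p-value), the classical ECI, CCC, ECIcor, CCCmax and
#' CCCcor with K = round(T/(2*tauS)), and the JSSI. By default the expected
#' chance count is the analytic stationary-Poisson value 2*tauS*n1*n2/T;
#' with `expectedMode = "ccg-flank"` it is instead estimated from the mean
#' count of off-center cross-correlogram bins whose |lag| lies in
#' `flankRange` (in units of tauS).
#'
#' @param pair a [PairedRecording-class].
#' @param params a [SynchronyParams-class].
#' @param expectedMode `"analytic"` (default) or `"ccg-flank"`.
#' @param flankRange numeric(2), flank window in multiples of tauS
#'   (default c(5, 25)).
#' @return named list: `n_c`, `r_c`, `expected`, `K`, `eci`, `eci_cor`,
#'   `ccc`, `ccc_max`, `ccc_cor`, `jssi`, `jbsi`, `z`, `p_value`.
#' @export
classicalIndices <- function(pair, params = SynchronyParams(1, 2),
                             expectedMode = c("analytic", "ccg-flank"),
                             flankRange = c(5, 25)) {
    stopifnot(is(pair, "PairedRecording"), is(params, "SynchronyParams"))
    expectedMode <- match.arg(expectedMode)
    n1 <- nSpikes(pair@reference)
    n2 <- nSpikes(pair@target)
    T <- epochDuration(pair)
    ts <- params@tauS
    res <- analyzeSynchrony(pair, params)
    nC <- res@nC
    K <- round(T / (2 * ts))
    expected <- if (expectedMode == "analytic") {
        expectedChanceCount(n1, n2, T, ts)
    } else {
        g <- computeCCG(pair, binWidth = 2 * ts,
                        maxLag = flankRange[2L] * ts + ts)
        flank <- abs(g$centers) >= flankRange[1L] * ts &
            abs(g$centers) <= flankRange[2L] * ts
        if (!any(flank)) stop("no CCG bins in the requested flank range")
        mean(g$counts[flank])
    }
    list(n_c = nC, r_c = nC / n1, expected = expected, K = K,
         eci = eci(nC, expected, n1),
         eci_cor = eciCor(nC, expected, n1),
         ccc = ccc(nC, n1, n2, K),
         ccc_max = cccMax(n1, n2, K),
         ccc_cor = cccCor(nC, n1, n2, K),
         jssi = if (is.na(res@z)) NA_real_ else jssi(res@z, n1, params),
         jbsi = res@jbsi, z = res@z, p_value = res@pValue)
}
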