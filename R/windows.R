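## Interval algebra for the jitter method: the union of synchrony windows
## around the target spikes and the overlap of each reference spike's jitter
## window with that union.

.times <- function(x) if (is(x, "SpikeTrain")) x@times else as.numeric(x)

#' Union of all synchrony windows of a target train
#'
#' Places a window of half-width `tauS` on each target spike and merges
#' overlapping or exactly abutting windows into disjoint segments, returned
#' as a d x 2 matrix of (start, end) rows sorted by start. The total length
#' never exceeds `2 * tauS * n2`.
#'
#' @param target a [SpikeTrain-class] or sorted numeric vector of target
#'   spike times (ms).
#' @param tauS synchrony span in ms (> 0).
#' @return numeric matrix with columns `start`, `end` (0 rows for an empty
#'   target).
#' @examples
#' mergeSynchronyWindows(c(10, 10.3), 0.25)  # windows fuse into one segment
#' @export
mergeSynchronyWindows <- function(target, tauS) {
    stopifnot(tauS > 0)
    t2 <- .times(target)
    if (is.unsorted(t2)) stop("target spike times must be sorted")
    n <- length(t2)
    if (n == 0L)
        return(matrix(numeric(0), 0L, 2L,
                      dimnames = list(NULL, c("start", "end"))))
    starts <- t2 - tauS
    ends <- t2 + tauS
    ## equal-width windows on sorted centres: segment breaks where the next
    ## window starts strictly after the current one ends (abutment merges)
    newSeg <- c(TRUE, starts[-1L] > ends[-n])
    first <- which(newSeg)
    last <- c(first[-1L] - 1L, n)
    cbind(start = starts[first], end = ends[last])
}

## membership of points in a disjoint sorted interval union (closed ends)
.inUnion <- function(x, U) {
    if (nrow(U) == 0L) return(rep(FALSE, length(x)))
    i <- findInterval(x, U[, 1L])
    i > 0L & x <= U[pmax(i, 1L), 2L]
}

## total length of U intersected with (-Inf, x]; vectorized over x
.unionCoverage <- function(x, U) {
    if (nrow(U) == 0L) return(numeric(length(x)))
    len <- U[, 2L] - U[, 1L]
    cum <- c(0, cumsum(len))
    i <- findInterval(x, U[, 1L])
    ii <- pmax(i, 1L)
    partial <- pmax(0, pmin(x, U[ii, 2L]) - U[ii, 1L])
    ifelse(i == 0L, 0, cum[ii] + partial)
}

#' Count observed spike coincidences
#'
#' The coincidence count N_C is the number of reference spikes lying within
#' `tauS` (closed interval, |dt| <= tauS) of at least one target spike; each
#' reference spike is counted at most once even when synchrony windows
#' overlap, so N_C <= n1. No time binning is involved.
#'
#' @param pair a [PairedRecording-class].
#' @param tauS synchrony span in ms (> 0).
#' @return integer coincidence count.
#' @examples
#' a <- SpikeTrain(c(10, 10.3), epochEnd = 20)
#' b <- SpikeTrain(c(10.1, 10.2), epochEnd = 20)
#' countCoincidences(PairedRecording(a, b), 0.5)  # 2
#' @export
countCoincidences <- function(pair, tauS) {
    stopifnot(is(pair, "PairedRecording"), tauS > 0)
    U <- mergeSynchronyWindows(pair@target, tauS)
    sum(.inUnion(spikeTimes(pair@reference), U))
}

#' Probability that a jittered spike lands in the synchrony-window union
#'
#' For a reference spike at `refSpike`, a uniform virtual jitter in
#' \[-tauJ, +tauJ\] lands inside the union `U` of synchrony windows with
#' probability equal to the overlap of the jitter window with `U`, divided
#' by the jitter-window width `2 * tauJ`. Jitter windows are not truncated
#' at the epoch boundaries.
#'
#' @param refSpike numeric vector of reference spike times (ms).
#' @param union matrix from [mergeSynchronyWindows()].
#' @param tauJ jitter span in ms (> 0).
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
jitterProbability <- function(refSpike, union, tauJ) {
    stopifnot(tauJ > 0)
    overlap <- .unionCoverage(refSpike + tauJ, union) -
        .unionCoverage(refSpike - tauJ, union)
    ## guard against floating-point overshoot at fully covered windows
    pmin(pmax(overlap / (2 * tauJ), 0), 1)
}

#' Per-spike jitter-synchrony probability vector
#'
#' Computes p_i, the probability that reference spike i remains (or
#' becomes) synchronous after a uniform jitter of +/-tauJ, for every
#' reference spike, via the synchrony-window union of the target train.
#' These probabilities fully determine the jitter-null distribution of the
#' coincidence count.
#'
#' @param pair a [PairedRecording-class].
#' @param params a [SynchronyParams-class].
#' @return numeric vector of length n1.
#' @export
probabilityVector <- function(pair, params) {
    stopifnot(is(pair, "PairedRecording"), is(params, "SynchronyParams"))
    U <- mergeSynchronyWindows(pair@target, params@tauS)
    jitterProbability(spikeTimes(pair@reference), U, params@tauJ)
}
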