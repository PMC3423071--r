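## Independent oracles the implementation is checked against. These stay
## deliberately naive: pairwise scans, full enumeration, closed forms for
## the isolated-window geometry.

## coincidence count by direct pairwise |dt| comparison
bruteCoincidences <- function(t1, t2, tauS) {
    sum(vapply(t1, function(x) any(abs(x - t2) <= tauS), logical(1)))
}

## per-spike jitter-synchrony probability from the closed form valid when
## synchrony windows are pairwise disjoint (target ISIs > 2*tauS): overlap
## with each window is 0 / 2*tauS / tauJ + tauS - |dt| by distance
closedFormP <- function(t1, t2, tauS, tauJ) {
    vapply(t1, function(x) {
        d <- abs(x - t2)
        ov <- ifelse(d >= tauJ + tauS, 0,
                     ifelse(d <= tauJ - tauS, 2 * tauS, tauJ + tauS - d))
        sum(ov) / (2 * tauJ)
    }, numeric(1))
}

## Poisson-binomial pmf by enumeration over all 2^n outcomes
brutePoissonBinomial <- function(p) {
    n <- length(p)
    out <- numeric(n + 1L)
    for (mask in 0:(2^n - 1L)) {
        bits <- as.integer(intToBits(mask))[seq_len(n)]
        k <- sum(bits)
        out[k + 1L] <- out[k + 1L] + prod(ifelse(bits == 1L, p, 1 - p))
    }
    out
}

## a pair in perfect synchrony: identical, isolated spikes
perfectPair <- function(n = 10, spacing = 100) {
    times <- seq_len(n) * spacing
    st <- SpikeTrain(times, epochEnd = (n + 1) * spacing)
    PairedRecording(st, st)
}

## extreme less-than-chance synchrony: each reference spike just beyond
## tauS from an isolated target spike
antiPair <- function(n = 10, spacing = 100, tauS = 1, eps = 1e-3) {
    tgt <- seq_len(n) * spacing
    ref <- tgt + tauS + eps
    PairedRecording(
        SpikeTrain(ref, epochEnd = (n + 1) * spacing),
        SpikeTrain(tgt, epochEnd = (n + 1) * spacing))
}

## random sparse pair on [0, T] with target ISIs kept > minGap
randomSparsePair <- function(n1, n2, T, minGap) {
    repeat {
        t2 <- sort(runif(n2, 0, T))
        if (all(diff(t2) > minGap)) break
    }
    t1 <- sort(runif(n1, 0, T))
    PairedRecording(SpikeTrain(t1, epochEnd = T),
                    SpikeTrain(t2, epochEnd = T))
}
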