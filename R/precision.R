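## Temporal-precision estimation: sweep the jitter span over a geometric
## grid at fixed alpha, average the Z and JBSI curves across pairs, and
## locate the significance crossing and the left-shoulder JBSI cutoff.

#' Jitter-span sweep over a geometric grid
#'
#' For tauJ values spanning \[tauJMin, tauJMax\] in 2^(1/stepsPerOctave)
#' multiples (default: 1 to 16 ms in sqrt(2) steps) with tauS = tauJ/alpha
#' fixed, analyzes every supplied pair at every grid point and records the
#' per-pair Z-scores and JBSI values. The averaged Z curve estimates firing
#' precision via [zThresholdCrossing()]; the averaged JBSI curve via
#' [jbsiCutoff()].
#'
#' @param pairs a [PairedRecording-class] or a list of them (averaging
#'   across pairs, e.g. repeated simulation runs).
#' @param tauJMin,tauJMax grid bounds in ms.
#' @param stepsPerOctave grid points per doubling (2 = sqrt(2) multiples).
#' @param alpha fixed tauJ/tauS ratio (default 2).
#' @return A [SweepResult-class].
#' @export
sweepPrecision <- function(pairs, tauJMin = 1, tauJMax = 16,
                           stepsPerOctave = 2, alpha = 2) {
    if (is(pairs, "PairedRecording")) pairs <- list(pairs)
    if (length(pairs) == 0L) stop("at least one pair is required")
    stopifnot(tauJMin > 0, tauJMax >= tauJMin, alpha >= 1)
    grid <- tauJMin * 2^(seq(0, log2(tauJMax / tauJMin),
                             by = 1 / stepsPerOctave))
    zv <- matrix(NA_real_, length(grid), length(pairs))
    jv <- matrix(NA_real_, length(grid), length(pairs))
    for (g in seq_along(grid)) {
        params <- SynchronyParams(tauS = grid[g] / alpha, tauJ = grid[g])
        for (k in seq_along(pairs)) {
            res <- analyzeSynchrony(pairs[[k]], params)
            zv[g, k] <- res@z
            jv[g, k] <- res@jbsi
        }
    }
    new("SweepResult", tauSGrid = grid / alpha, tauJGrid = grid,
        zValues = zv, jbsiValues = jv, alpha = as.numeric(alpha))
}

#' Jitter span at which the averaged Z curve crosses a threshold
#'
#' The smallest tauJ whose run-averaged Z-score reaches `zThreshold`
#' estimates the firing precision: below it, jitter is too small to disturb
#' the observed synchrony. The crossing is refined by linear interpolation
#' in (log tauJ, Z) between the bracketing grid points (the grid is
#' geometric). If the entire curve is already above threshold the smallest
#' grid value is returned with `atFloor = TRUE`; if it never reaches the
#' threshold, `found = FALSE`.
#'
#' @param sweep a [SweepResult-class].
#' @param zThreshold positive significance threshold (default 3.3,
#'   two-tailed p = 0.001).
#' @return list with `tauJ` (ms or NA), `found`, `atFloor`.
#' @export
zThresholdCrossing <- function(sweep, zThreshold = 3.3) {
    stopifnot(is(sweep, "SweepResult"), zThreshold > 0)
    z <- zCurve(sweep)
    g <- sweep@tauJGrid
    above <- which(!is.na(z) & z >= zThreshold)
    if (!length(above))
        return(list(tauJ = NA_real_, found = FALSE, atFloor = FALSE))
    i <- above[1L]
    if (i == 1L)
        return(list(tauJ = g[1L], found = TRUE, atFloor = TRUE))
    f <- (zThreshold - z[i - 1L]) / (z[i] - z[i - 1L])
    tauJ <- exp(log(g[i - 1L]) + f * (log(g[i]) - log(g[i - 1L])))
    list(tauJ = tauJ, found = TRUE, atFloor = FALSE)
}

#' Left-shoulder cutoff of the averaged JBSI curve
#'
#' The JBSI-vs-tauS curve slopes shallowly to the right of its peak but
#' drops steeply to the left once tauS falls below the temporal precision
#' of the synchrony. The cutoff is formalized as the smallest grid tauS at
#' which the averaged curve reaches `fraction` of its maximum (default
#' 90 percent).
#'
#' @param sweep a [SweepResult-class].
#' @param fraction fraction of the curve maximum defining the shoulder,
#'   in (0, 1).
#' @return list with `tauS` (ms or NA) and `found`.
#' @export
jbsiCutoff <- function(sweep, fraction = 0.9) {
    stopifnot(is(sweep, "SweepResult"), fraction > 0, fraction < 1)
    j <- jbsiCurve(sweep)
    g <- sweep@tauSGrid
    if (all(is.na(j)) || max(j, na.rm = TRUE) <= 0)
        return(list(tauS = NA_real_, found = FALSE))
    thr <- fraction * max(j, na.rm = TRUE)
    i <- which(!is.na(j) & j >= thr)[1L]
    list(tauS = g[i], found = TRUE)
}
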