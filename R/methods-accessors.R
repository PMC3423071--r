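#' @rdname SpikeTrain-class
#' @aliases spikeTimes,SpikeTrain-method
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)

#' @rdname SpikeTrain-class
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))

#' @rdname SpikeTrain-class
setMethod("epochStart", "SpikeTrain", function(x) x@epochStart)

#' @rdname SpikeTrain-class
setMethod("epochEnd", "SpikeTrain", function(x) x@epochEnd)

#' @rdname SpikeTrain-class
setMethod("epochDuration", "SpikeTrain",
          function(x) x@epochEnd - x@epochStart)

#' @rdname SpikeTrain-class
setMethod("firingRate", "SpikeTrain",
          function(x) 1000 * length(x@times) / (x@epochEnd - x@epochStart))

setMethod("show", "SpikeTrain", function(object) {
    cat(sprintf("SpikeTrain: %d spikes on [%g, %g] ms (%.2f Hz)\n",
                length(object@times), object@epochStart, object@epochEnd,
                firingRate(object)))
})

#' @rdname PairedRecording-class
setMethod("referenceTrain", "PairedRecording", function(x) x@reference)

#' @rdname PairedRecording-class
setMethod("targetTrain", "PairedRecording", function(x) x@target)

#' @rdname PairedRecording-class
setMethod("epochDuration", "PairedRecording",
          function(x) epochDuration(x@reference))

setMethod("show", "PairedRecording", function(object) {
    cat(sprintf(
        "PairedRecording: n1 = %d (reference), n2 = %d (target), T = %g ms\n",
        nSpikes(object@reference), nSpikes(object@target),
        epochDuration(object)))
})

#' @rdname SynchronyParams-class
setMethod("tauS", "SynchronyParams", function(x) x@tauS)

#' @rdname SynchronyParams-class
setMethod("tauJ", "SynchronyParams", function(x) x@tauJ)

#' @rdname SynchronyParams-class
setMethod("alphaRatio", "SynchronyParams", function(x) x@tauJ / x@tauS)

#' @rdname SynchronyParams-class
setMethod("betaFactor", "SynchronyParams", function(x) {
    a <- x@tauJ / x@tauS
    if (a <= 2) 2 else a / (a - 1)
})

setMethod("show", "SynchronyParams", function(object) {
    cat(sprintf(
        "SynchronyParams: tauS = %g ms, tauJ = %g ms (alpha = %g, beta = %g)\n",
        object@tauS, object@tauJ, alphaRatio(object), betaFactor(object)))
})

#' @rdname SynchronyResult-class
setMethod("coincidenceCount", "SynchronyResult", function(x) x@nC)

#' @rdname SynchronyResult-class
setMethod("coincidenceRate", "SynchronyResult", function(x) x@nC / x@n1)

#' @rdname SynchronyResult-class
setMethod("probVector", "SynchronyResult", function(x) x@p)

#' @rdname SynchronyResult-class
setMethod("expectedJittered", "SynchronyResult",
          function(x) x@expectedJittered)

#' @rdname SynchronyResult-class
setMethod("jitteredVariance", "SynchronyResult", function(x) x@variance)

#' @rdname SynchronyResult-class
setMethod("zValue", "SynchronyResult", function(x) x@z)

#' @rdname SynchronyResult-class
setMethod("jbsiValue", "SynchronyResult", function(x) x@jbsi)

#' @rdname SynchronyResult-class
setMethod("tauS", "SynchronyResult", function(x) x@params@tauS)

#' @rdname SynchronyResult-class
setMethod("tauJ", "SynchronyResult", function(x) x@params@tauJ)

setMethod("show", "SynchronyResult", function(object) {
    cat("SynchronyResult\n")
    cat(sprintf("  n1 = %d, n2 = %d, T = %g ms; tauS = %g ms, tauJ = %g ms\n",
                object@n1, object@n2, object@T,
                object@params@tauS, object@params@tauJ))
    cat(sprintf("  N_C = %d (R_C = %.4f); <N_C^J> = %.3f, Var = %.3f\n",
                object@nC, object@nC / object@n1, object@expectedJittered,
                object@variance))
    cat(sprintf("  Z = %.3f, p = %.4g, JBSI = %.4f\n",
                object@z, object@pValue, object@jbsi))
})

#' @rdname SweepResult-class
setMethod("tauS", "SweepResult", function(x) x@tauSGrid)

#' @rdname SweepResult-class
setMethod("tauJ", "SweepResult", function(x) x@tauJGrid)

#' @rdname SweepResult-class
setMethod("zCurve", "SweepResult",
          function(x) rowMeans(x@zValues, na.rm = TRUE))

#' @rdname SweepResult-class
setMethod("jbsiCurve", "SweepResult",
          function(x) rowMeans(x@jbsiValues, na.rm = TRUE))

.rowSem <- function(m) {
    n <- rowSums(!is.na(m))
    out <- apply(m, 1L, stats::sd, na.rm = TRUE) / sqrt(n)
    out[n < 2] <- NA_real_
    out
}

#' Tabulate a sweep
#'
#' @param x a [SweepResult-class].
#' @param ... ignored.
#' @return data.frame with columns tau_s_ms, tau_j_ms, z_mean, z_sem,
#'   jbsi_mean, jbsi_sem.
#' @export
as.data.frame.SweepResult <- function(x, ...) {
    data.frame(tau_s_ms = x@tauSGrid, tau_j_ms = x@tauJGrid,
               z_mean = zCurve(x), z_sem = .rowSem(x@zValues),
               jbsi_mean = jbsiCurve(x), jbsi_sem = .rowSem(x@jbsiValues))
}

setMethod("show", "SweepResult", function(object) {
    cat(sprintf("SweepResult: %d grid points x %d pairs (alpha = %g)\n",
                length(object@tauJGrid), ncol(object@zValues), object@alpha))
    print(as.data.frame.SweepResult(object), digits = 4)
})
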