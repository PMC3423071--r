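#' @rdname SpikeTrain-class
#' @param object,x a package object.
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname SpikeTrain-class
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' @rdname SpikeTrain-class
#' @export
setGeneric("epochStart", function(x) standardGeneric("epochStart"))

#' @rdname SpikeTrain-class
#' @export
setGeneric("epochEnd", function(x) standardGeneric("epochEnd"))

#' @rdname SpikeTrain-class
#' @export
setGeneric("epochDuration", function(x) standardGeneric("epochDuration"))

#' @rdname SpikeTrain-class
#' @export
setGeneric("firingRate", function(x) standardGeneric("firingRate"))

#' @rdname PairedRecording-class
#' @export
setGeneric("referenceTrain", function(x) standardGeneric("referenceTrain"))

#' @rdname PairedRecording-class
#' @export
setGeneric("targetTrain", function(x) standardGeneric("targetTrain"))

#' @rdname SynchronyParams-class
#' @export
setGeneric("tauS", function(x) standardGeneric("tauS"))

#' @rdname SynchronyParams-class
#' @export
setGeneric("tauJ", function(x) standardGeneric("tauJ"))

#' @rdname SynchronyParams-class
#' @export
setGeneric("alphaRatio", function(x) standardGeneric("alphaRatio"))

#' @rdname SynchronyParams-class
#' @export
setGeneric("betaFactor", function(x) standardGeneric("betaFactor"))

#' @rdname SynchronyResult-class
#' @export
setGeneric("coincidenceCount", function(x) standardGeneric("coincidenceCount"))

#' @rdname SynchronyResult-class
#' @export
setGeneric("coincidenceRate", function(x) standardGeneric("coincidenceRate"))

#' @rdname SynchronyResult-class
#' @export
setGeneric("probVector", function(x) standardGeneric("probVector"))

#' @rdname SynchronyResult-class
#' @export
setGeneric("expectedJittered", function(x) standardGeneric("expectedJittered"))

#' @rdname SynchronyResult-class
#' @export
setGeneric("jitteredVariance", function(x) standardGeneric("jitteredVariance"))

#' @rdname SynchronyResult-class
#' @export
setGeneric("zValue", function(x) standardGeneric("zValue"))

#' @rdname SynchronyResult-class
#' @export
setGeneric("jbsiValue", function(x) standardGeneric("jbsiValue"))

#' @rdname SweepResult-class
#' @export
setGeneric("zCurve", function(x) standardGeneric("zCurve"))

#' @rdname SweepResult-class
#' @export
setGeneric("jbsiCurve", function(x) standardGeneric("jbsiCurve"))
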