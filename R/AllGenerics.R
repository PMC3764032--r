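#' @include AllGenerics.R
NULL

#' Accessors for session and result objects
#'
#' Small family of generics shared by the data containers:
#' \code{trialTable} returns the per-trial metadata table,
#' \code{lfpData} the trial x site x time LFP array,
#' \code{spikeCounts} the trial x site x epoch spike-count array,
#' \code{samplingRate} the sampling rate in Hz, \code{nSites} and
#' \code{nTrials} the respective dimensions, \code{powerArray} the
#' trial x site x band x epoch band-power array, \code{bandTable}
#' the band definition table and \code{resultTable} the tidy results
#' data frame of a decoding run.
#'
#' @param x a \linkS4class{SessionRecording}, \linkS4class{BandPowerTable}
#'   or \linkS4class{DecodingResult} object.
#' @return See the individual descriptions above.
#' @name accessors
#' @aliases trialTable lfpData spikeCounts samplingRate nSites nTrials
#'   powerArray bandTable resultTable repScores
NULL

#' @rdname accessors
#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))

#' @rdname accessors
#' @export
setGeneric("lfpData", function(x) standardGeneric("lfpData"))

#' @rdname accessors
#' @export
setGeneric("spikeCounts", function(x) standardGeneric("spikeCounts"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("powerArray", function(x) standardGeneric("powerArray"))

#' @rdname accessors
#' @export
setGeneric("bandTable", function(x) standardGeneric("bandTable"))

#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname accessors
#' @export
setGeneric("repScores", function(x) standardGeneric("repScores"))
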