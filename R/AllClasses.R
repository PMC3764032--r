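#' @include AllGenerics.R
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Generative parameterisation of a synthetic adaptation session
#'
#' A \code{SimulationConfig} holds every parameter of the synthetic laminar
#' LFP/MUA session generator: geometry (sites, trials), timing (all in ms),
#' per-band stimulus selectivity, band-specific adaptation gains, background
#' noise structure and spiking parameters. See \code{\link{simulationConfig}}
#' for defaults and units.
#'
#' @slot nSites number of simultaneously recorded laminar sites.
#' @slot nTrialsPerSequence unaborted trials per sequence type (AA, BB, AB, BA).
#' @slot samplingRate sampling rate in Hz.
#' @slot stimDuration,isi,preStim,postStim epoch durations in ms.
#' @slot bandGains named list, one \code{c(A=, B=)} nominal band-power gain
#'   pair (a.u.^2) per frequency band.
#' @slot repetitionGain named numeric, multiplicative factor applied to
#'   test-epoch band power in repetition (AA/BB) trials; < 1 means
#'   repetition suppression.
#' @slot crossAdaptationGain named numeric, same for alternation (AB/BA)
#'   trials (cross-adaptation).
#' @slot noiseExponent spectral slope of the 1/f^a background.
#' @slot backgroundAmplitude standard deviation (a.u.) of the background.
#' @slot lineNoiseAmplitude amplitude (a.u.) of the 50 Hz line component.
#' @slot siteGainSD log-normal spread of overall per-site responsiveness
#'   (applied to both stimuli alike; 0 = identical sites).
#' @slot siteSelectivitySD relative spread of per-site stimulus
#'   selectivity around the nominal gain ratio (0 = every site carries
#'   exactly the nominal contrast).
#' @slot sharedNoiseFraction fraction of band-limited oscillation variance
#'   shared across sites (the rest is private per site).
#' @slot spikeRate named numeric \code{c(A=, B=)}, mean multi-unit firing
#'   rate in Hz per site for each stimulus.
#' @slot spikeAdaptationFactor multiplicative factor on test-epoch spike
#'   rate in repetition trials.
#' @slot abortProb probability that a trial is aborted (flagged, never
#'   analysed).
#' @slot inputRange declared representable signal range \code{c(min, max)}
#'   in a.u., used by clipping-based trial rejection.
#' @slot seed integer seed making the whole session reproducible.
#' @seealso \code{\link{simulationConfig}}, \code{\link{simulateSession}}
#' @export
setClass("SimulationConfig",
  representation(
    nSites = "integer",
    nTrialsPerSequence = "integer",
    samplingRate = "numeric",
    stimDuration = "numeric",
    isi = "numeric",
    preStim = "numeric",
    postStim = "numeric",
    bandGains = "list",
    repetitionGain = "numeric",
    crossAdaptationGain = "numeric",
    noiseExponent = "numeric",
    backgroundAmplitude = "numeric",
    lineNoiseAmplitude = "numeric",
    siteGainSD = "numeric",
    siteSelectivitySD = "numeric",
    sharedNoiseFraction = "numeric",
    spikeRate = "numeric",
    spikeAdaptationFactor = "numeric",
    abortProb = "numeric",
    inputRange = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (length(object@nSites) != 1L || object@nSites < 1L)
    msg <- c(msg, "nSites must be a single positive integer")
  if (length(object@nTrialsPerSequence) != 1L || object@nTrialsPerSequence < 4L)
    msg <- c(msg, "nTrialsPerSequence must be >= 4")
  durs <- c(object@samplingRate, object@stimDuration, object@isi,
            object@preStim, object@postStim)
  if (any(!is.finite(durs)) || any(durs[1:3] <= 0) || any(durs[4:5] < 0))
    msg <- c(msg, "sampling rate and stimulus/ISI durations must be positive")
  bn <- names(object@bandGains)
  if (is.null(bn) || any(!nzchar(bn)))
    msg <- c(msg, "bandGains must be a named list")
  for (g in object@bandGains) {
    if (length(g) != 2L || any(!is.finite(g)) || any(g < 0))
      msg <- c(msg, "each band gain must be a finite non-negative pair (A, B)")
  }
  for (nm in c("repetitionGain", "crossAdaptationGain")) {
    v <- slot(object, nm)
    if (!setequal(names(v), bn) || any(!is.finite(v)) || any(v < 0))
      msg <- c(msg, sprintf("%s must be finite, >= 0 and named per band", nm))
  }
  if (!is.finite(object@noiseExponent) || object@noiseExponent < 0)
    msg <- c(msg, "noiseExponent must be finite and >= 0")
  for (nm in c("backgroundAmplitude", "lineNoiseAmplitude", "siteGainSD",
               "siteSelectivitySD"))
    if (!is.finite(slot(object, nm)) || slot(object, nm) < 0)
      msg <- c(msg, sprintf("%s must be finite and >= 0", nm))
  if (object@sharedNoiseFraction < 0 || object@sharedNoiseFraction > 1)
    msg <- c(msg, "sharedNoiseFraction must be in [0, 1]")
  if (!setequal(names(object@spikeRate), c("A", "B")) ||
      any(!is.finite(object@spikeRate)) || any(object@spikeRate < 0))
    msg <- c(msg, "spikeRate must be a finite non-negative pair named A, B")
  if (!is.finite(object@spikeAdaptationFactor) || object@spikeAdaptationFactor < 0)
    msg <- c(msg, "spikeAdaptationFactor must be finite and >= 0")
  if (object@abortProb < 0 || object@abortProb >= 1)
    msg <- c(msg, "abortProb must be in [0, 1)")
  if (length(object@inputRange) != 2L || diff(object@inputRange) <= 0)
    msg <- c(msg, "inputRange must be c(min, max) with min < max")
  if (length(msg)) msg else TRUE
})

#' All trials of one simulated or recorded penetration
#'
#' Container for the raw data of a single penetration: the LFP tensor
#' (trial x site x time sample), optional per-epoch spike counts, the trial
#' table and acquisition metadata. The time axis covers
#' pre-stimulus baseline, adapter, inter-stimulus interval, test stimulus
#' and a post-test tail, at \code{samplingRate} Hz.
#'
#' @slot lfp numeric array, trial x site x time (a.u.).
#' @slot spikes integer array trial x site x epoch (epochs
#'   \code{adapter}, \code{test}) or \code{NULL}.
#' @slot trials data frame with columns \code{trial_id},
#'   \code{sequence_type}, \code{adapter_stim}, \code{test_stim},
#'   \code{aborted}.
#' @slot samplingRate Hz.
#' @slot siteSpacing inter-contact spacing in micrometres (metadata only).
#' @slot inputRange declared representable range \code{c(min, max)} (a.u.);
#'   required by clipping-based trial rejection.
#' @slot onsets named numeric, stimulus onset times in ms
#'   (\code{adapter}, \code{test}) relative to trace start.
#' @slot groundTruth list with the realised per-site band gains and spike
#'   rates of the generator (empty for real recordings).
#' @seealso \code{\link{simulateSession}}, \code{\link{rejectClippedTrials}},
#'   \code{\link{bandPower}}
#' @export
setClass("SessionRecording",
  representation(
    lfp = "array",
    spikes = "arrayOrNULL",
    trials = "data.frame",
    samplingRate = "numeric",
    siteSpacing = "numeric",
    inputRange = "numeric",
    onsets = "numeric",
    groundTruth = "list"
  )
)

setValidity("SessionRecording", function(object) {
  msg <- character(0)
  d <- dim(object@lfp)
  if (length(d) != 3L)
    msg <- c(msg, "lfp must be a trial x site x time array")
  else {
    if (d[1L] != nrow(object@trials))
      msg <- c(msg, "lfp trial dimension must match the trial table")
    if (any(!is.finite(object@lfp)))
      msg <- c(msg, "lfp contains non-finite samples")
  }
  need <- c("trial_id", "sequence_type", "adapter_stim", "test_stim", "aborted")
  if (!all(need %in% names(object@trials)))
    msg <- c(msg, paste("trial table must have columns:",
                        paste(need, collapse = ", ")))
  if (!all(c("adapter", "test") %in% names(object@onsets)))
    msg <- c(msg, "onsets must be named 'adapter' and 'test' (ms)")
  if (!is.null(object@spikes)) {
    ds <- dim(object@spikes)
    if (length(ds) != 3L || ds[1L] != nrow(object@trials) || ds[3L] != 2L)
      msg <- c(msg, "spikes must be a trial x site x 2 (adapter, test) array")
  }
  if (length(msg)) msg else TRUE
})

#' Per-trial, per-site, per-band scalar power
#'
#' Band power averaged over the analysis window and over the integer
#' wavelet-grid frequencies within each band, for both the adapter and the
#' test epoch of every unaborted, unrejected trial.
#'
#' @slot power numeric array trial x site x band x epoch (a.u.^2); epochs
#'   are \code{adapter} and \code{test}.
#' @slot bands data frame with columns \code{name}, \code{lo}, \code{hi}
#'   (Hz, inclusive on the integer frequency grid).
#' @slot trials trial table of the retained trials.
#' @slot window analysis window \code{c(start, end)} in ms relative to
#'   stimulus onset (half-open).
#' @seealso \code{\link{bandPower}}, \code{\link{buildConditions}}
#' @export
setClass("BandPowerTable",
  representation(
    power = "array",
    bands = "data.frame",
    trials = "data.frame",
    window = "numeric"
  )
)

setValidity("BandPowerTable", function(object) {
  msg <- character(0)
  d <- dim(object@power)
  if (length(d) != 4L)
    msg <- c(msg, "power must be trial x site x band x epoch")
  else {
    if (d[1L] != nrow(object@trials))
      msg <- c(msg, "power trial dimension must match trial table")
    if (d[3L] != nrow(object@bands))
      msg <- c(msg, "power band dimension must match band table")
    if (d[4L] != 2L)
      msg <- c(msg, "power must have adapter and test epochs")
    if (any(!is.finite(object@power)) || any(object@power < 0))
      msg <- c(msg, "band power must be finite and non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Result of decoding one penetration
#'
#' Tidy per-band, per-condition mean cross-validated accuracies of one
#' penetration plus the underlying per-repetition scores.
#'
#' @slot table data frame with columns \code{penetration}, \code{band},
#'   \code{condition}, \code{mean_accuracy}, \code{shuffle_mean},
#'   \code{n_tot}, \code{n_sites}, \code{seed} and the per-sub-dataset
#'   means \code{sub1_accuracy}, \code{sub2_accuracy}.
#' @slot repScores named list of per-repetition accuracy vectors (%),
#'   one per band x condition.
#' @slot params list echoing the decoding parameters.
#' @seealso \code{\link{decodeSession}}
#' @export
setClass("DecodingResult",
  representation(
    table = "data.frame",
    repScores = "list",
    params = "list"
  )
)

setValidity("DecodingResult", function(object) {
  msg <- character(0)
  tb <- object@table
  if (nrow(tb)) {
    if (any(tb$mean_accuracy < 0 | tb$mean_accuracy > 100, na.rm = TRUE))
      msg <- c(msg, "accuracies must lie in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})

## ---- accessors ------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("trialTable", "SessionRecording", function(x) x@trials)

#' @rdname accessors
#' @export
setMethod("trialTable", "BandPowerTable", function(x) x@trials)

#' @rdname accessors
#' @export
setMethod("lfpData", "SessionRecording", function(x) x@lfp)

#' @rdname accessors
#' @export
setMethod("spikeCounts", "SessionRecording", function(x) x@spikes)

#' @rdname accessors
#' @export
setMethod("samplingRate", "SessionRecording", function(x) x@samplingRate)

#' @rdname accessors
#' @export
setMethod("nSites", "SessionRecording", function(x) dim(x@lfp)[2L])

#' @rdname accessors
#' @export
setMethod("nSites", "BandPowerTable", function(x) dim(x@power)[2L])

#' @rdname accessors
#' @export
setMethod("nTrials", "SessionRecording", function(x) nrow(x@trials))

#' @rdname accessors
#' @export
setMethod("nTrials", "BandPowerTable", function(x) nrow(x@trials))

#' @rdname accessors
#' @export
setMethod("powerArray", "BandPowerTable", function(x) x@power)

#' @rdname accessors
#' @export
setMethod("bandTable", "BandPowerTable", function(x) x@bands)

#' @rdname accessors
#' @export
setMethod("resultTable", "DecodingResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("repScores", "DecodingResult", function(x) x@repScores)

## ---- show -----------------------------------------------------------------

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  %d sites, %d trials per sequence type (AA/BB/AB/BA)\n",
              object@nSites, object@nTrialsPerSequence))
  cat(sprintf("  fs = %g Hz; pre %g | adapter %g | ISI %g | test %g | post %g ms\n",
              object@samplingRate, object@preStim, object@stimDuration,
              object@isi, object@stimDuration, object@postStim))
  cat(sprintf("  bands: %s\n", paste(names(object@bandGains), collapse = ", ")))
  cat(sprintf("  repetition gains: %s\n",
              paste(sprintf("%s=%.2f", names(object@repetitionGain),
                            object@repetitionGain), collapse = " ")))
  cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "SessionRecording", function(object) {
  d <- dim(object@lfp)
  cat("SessionRecording\n")
  cat(sprintf("  %d trials x %d sites x %d samples at %g Hz\n",
              d[1L], d[2L], d[3L], object@samplingRate))
  cat(sprintf("  aborted trials: %d; spikes: %s\n",
              sum(object@trials$aborted),
              if (is.null(object@spikes)) "absent" else "present"))
  tt <- table(object@trials$sequence_type[!object@trials$aborted])
  cat("  unaborted per sequence:",
      paste(sprintf("%s=%d", names(tt), tt), collapse = " "), "\n")
})

setMethod("show", "BandPowerTable", function(object) {
  d <- dim(object@power)
  cat("BandPowerTable\n")
  cat(sprintf("  %d trials x %d sites x %d bands x 2 epochs\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  window: [%g, %g) ms post-onset\n",
              object@window[1L], object@window[2L]))
  cat("  bands:", paste(sprintf("%s (%g-%g Hz)", object@bands$name,
                                object@bands$lo, object@bands$hi),
                        collapse = ", "), "\n")
})

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult\n")
  tb <- object@table
  if (nrow(tb)) {
    cat(sprintf("  penetration %s: %d band x condition cells, N_tot = %d, %d sites\n",
                tb$penetration[1L], nrow(tb), tb$n_tot[1L], tb$n_sites[1L]))
    wide <- tapply(tb$mean_accuracy, list(tb$band, tb$condition), identity)
    print(round(wide, 1))
  } else cat("  (empty)\n")
})
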