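#' @include AllClasses.R bands.R
NULL

## Run code under a fixed seed, restoring the caller's RNG state afterwards.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

## Derive a stream of per-task seeds from one master seed (all < 2^31).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Construct a synthetic-session configuration
#'
#' Builds a validated \linkS4class{SimulationConfig}. The defaults emulate
#' the recording conditions of a laminar penetration in an adaptation
#' paradigm: 16 sites at 1 kHz, 120 unaborted trials per sequence type
#' (AA, BB, AB, BA), 500 ms adapter / 500 ms blank / 500 ms test preceded by
#' a 500 ms fixation baseline. Stimulus selectivity is expressed as
#' per-band band-power gain pairs \code{c(A=, B=)}; repetition suppression
#' is confined by default to the middle and high gamma bands
#' (multiplicative test-epoch gains < 1 in repetition trials) while
#' cross-adaptation in alternation trials is near unity, mirroring the
#' qualitative band specificity of adaptation effects on decodability.
#' The default gain magnitudes are free parameters of the generator chosen
#' so that decoding accuracy is highest for alpha/beta and lowest for the
#' middle gamma band.
#'
#' @param nSites number of laminar sites.
#' @param nTrialsPerSequence unaborted trials per sequence type.
#' @param samplingRate Hz.
#' @param stimDuration,isi,preStim,postStim epoch durations, ms.
#' @param bandGains named list of \code{c(A=, B=)} band-power gains
#'   (a.u.^2).
#' @param repetitionGain named per-band multiplicative factor on
#'   test-epoch band power in repetition trials (< 1 = suppression).
#' @param crossAdaptationGain same for alternation trials.
#' @param noiseExponent slope a of the 1/f^a background.
#' @param backgroundAmplitude background standard deviation, a.u.
#' @param lineNoiseAmplitude 50 Hz line amplitude, a.u.
#' @param siteGainSD log-normal sd of overall per-site responsiveness.
#' @param siteSelectivitySD relative spread of per-site selectivity
#'   around the nominal gain ratio.
#' @param sharedNoiseFraction fraction of oscillation variance shared
#'   across sites.
#' @param spikeRate \code{c(A=, B=)} mean multi-unit rate, Hz.
#' @param spikeAdaptationFactor factor on test-epoch rate in repetition
#'   trials.
#' @param abortProb per-trial abort probability.
#' @param inputRange declared representable signal range, a.u.
#' @param seed integer master seed.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nTrialsPerSequence = 8, seed = 1)
#' cfg
#' @export
simulationConfig <- function(nSites = 16L,
                             nTrialsPerSequence = 120L,
                             samplingRate = 1000,
                             stimDuration = 500,
                             isi = 500,
                             preStim = 500,
                             postStim = 500,
                             bandGains = list(
                               alpha = c(A = 0.52, B = 0.28),
                               beta = c(A = 0.38, B = 0.26),
                               low_gamma = c(A = 0.29, B = 0.25),
                               middle_gamma = c(A = 0.22, B = 0.20),
                               high_gamma = c(A = 0.17, B = 0.138)
                             ),
                             repetitionGain = c(alpha = 1, beta = 1,
                                                low_gamma = 1,
                                                middle_gamma = 0.65,
                                                high_gamma = 0.55),
                             crossAdaptationGain = c(alpha = 1, beta = 1,
                                                     low_gamma = 1,
                                                     middle_gamma = 0.97,
                                                     high_gamma = 0.97),
                             noiseExponent = 1,
                             backgroundAmplitude = 1,
                             lineNoiseAmplitude = 0.5,
                             siteGainSD = 0.25,
                             siteSelectivitySD = 0.5,
                             sharedNoiseFraction = 0.5,
                             spikeRate = c(A = 18, B = 15),
                             spikeAdaptationFactor = 0.7,
                             abortProb = 0.05,
                             inputRange = c(-500, 500),
                             seed = 1L) {
  methods::new("SimulationConfig",
    nSites = as.integer(nSites),
    nTrialsPerSequence = as.integer(nTrialsPerSequence),
    samplingRate = samplingRate,
    stimDuration = stimDuration, isi = isi,
    preStim = preStim, postStim = postStim,
    bandGains = bandGains,
    repetitionGain = repetitionGain,
    crossAdaptationGain = crossAdaptationGain,
    noiseExponent = noiseExponent,
    backgroundAmplitude = backgroundAmplitude,
    lineNoiseAmplitude = lineNoiseAmplitude,
    siteGainSD = siteGainSD,
    siteSelectivitySD = siteSelectivitySD,
    sharedNoiseFraction = sharedNoiseFraction,
    spikeRate = spikeRate,
    spikeAdaptationFactor = spikeAdaptationFactor,
    abortProb = abortProb,
    inputRange = inputRange,
    seed = as.integer(seed))
}

seqAdapter <- function(type) substr(type, 1L, 1L)
seqTest <- function(type) substr(type, 2L, 2L)
isRepetition <- function(type) type %in% c("AA", "BB")

#' Generate a pseudorandomised adaptation trial table
#'
#' Produces the trial sequence of one session: \code{nTrialsPerSequence}
#' unaborted trials of each sequence type AA, BB, AB and BA in
#' pseudorandom order under the constraint that the adapter stimulus of a
#' trial always differs from the last presented stimulus of the preceding
#' (aborted or unaborted) trial. Aborted trials are inserted with
#' probability \code{abortProb}, flagged, and do not count towards the
#' per-type quota; an aborted trial is assumed to end during or after its
#' adapter, so its adapter is the last presented stimulus.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return data frame with columns \code{trial_id}, \code{sequence_type},
#'   \code{adapter_stim}, \code{test_stim}, \code{aborted}.
#' @examples
#' tt <- generateTrialTable(simulationConfig(nTrialsPerSequence = 5,
#'                                           abortProb = 0, seed = 7))
#' table(tt$sequence_type)
#' @export
generateTrialTable <- function(config) {
  stopifnot(methods::is(config, "SimulationConfig"))
  methods::validObject(config)
  withSeed(config@seed, generateTrialTableImpl(config))
}

generateTrialTableImpl <- function(config,
                                   quota = rep(config@nTrialsPerSequence,
                                               4L)) {
  types <- c("AA", "BB", "AB", "BA")
  for (attempt in seq_len(1000L)) {
    counts <- stats::setNames(quota, types)
    lastStim <- NA_character_
    seqType <- character(0)
    aborted <- logical(0)
    ok <- TRUE
    while (sum(counts) > 0L) {
      abort <- stats::runif(1L) < config@abortProb
      avail <- if (abort) types else types[counts > 0L]
      allowed <- avail[is.na(lastStim) | seqAdapter(avail) != lastStim]
      if (!length(allowed)) { ok <- FALSE; break }
      w <- if (abort) rep(1, length(allowed)) else counts[allowed]
      ty <- if (length(allowed) == 1L) allowed else
        sample(allowed, 1L, prob = w)
      seqType <- c(seqType, ty)
      aborted <- c(aborted, abort)
      if (abort) {
        lastStim <- seqAdapter(ty)          # abort during/after adapter
      } else {
        counts[ty] <- counts[ty] - 1L
        lastStim <- seqTest(ty)
      }
    }
    if (ok) {
      n <- length(seqType)
      return(data.frame(
        trial_id = seq_len(n),
        sequence_type = seqType,
        adapter_stim = seqAdapter(seqType),
        test_stim = seqTest(seqType),
        aborted = aborted,
        stringsAsFactors = FALSE))
    }
  }
  stop("sequencing constraint unsatisfiable for the requested trial counts")
}

## ---- band-limited carrier machinery ---------------------------------------

.filterCache <- new.env(parent = emptyenv())

## Butterworth band-pass coefficients plus the variance gain of
## forward-backward filtering unit-variance white noise, cached per band.
bandFilter <- function(lo, hi, fs) {
  key <- sprintf("%g-%g-%g", lo, hi, fs)
  hit <- .filterCache[[key]]
  if (!is.null(hit)) return(hit)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  fr <- signal::freqz(bf, n = 4096)
  varGain <- mean(Mod(fr$h)^4)            # filtfilt applies |H|^2
  out <- list(filt = bf, varGain = varGain)
  assign(key, out, envir = .filterCache)
  out
}

## Unit-variance band-limited Gaussian carrier of length n.
bandCarrier <- function(n, lo, hi, fs) {
  bf <- bandFilter(lo, hi, fs)
  x <- signal::filtfilt(bf$filt, stats::rnorm(n))
  x / sqrt(bf$varGain)
}

## 1/f^a background noise, unit variance, length n.
pinkNoise <- function(n, exponent, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)                    # two-sided frequency axis
  shape <- c(0, f[-1L]^(-exponent / 2))
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

## Amplitude envelope for one epoch with raised-cosine 20 ms ramps.
epochEnvelope <- function(n, startIdx, len, rampSamples) {
  env <- numeric(n)
  idx <- seq.int(startIdx, length.out = len)
  shape <- rep(1, len)
  r <- min(rampSamples, floor(len / 2))
  if (r > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    shape[seq_len(r)] <- ramp
    shape[len + 1L - seq_len(r)] <- rev(ramp)
  }
  env[idx] <- shape
  env
}

## Realise per-site selectivity. Each site gets (a) an overall
## responsiveness factor applied to both stimuli alike (log-normal,
## siteGainSD) and (b) its own stimulus contrast, drawn around the
## nominal log gain ratio with relative spread siteSelectivitySD, so
## sites carry partially independent stimulus information while the
## population-average contrast stays at the nominal value.
realizePair <- function(pair, nSites, gainSD, selSD) {
  f <- exp(stats::rnorm(nSites, 0, gainSD))
  if (any(pair <= 0))                     # degenerate gains: no log-ratio
    return(cbind(A = f * pair[[1L]], B = f * pair[[2L]]))
  gm <- sqrt(prod(pair))
  logRatio <- log(pair[[1L]] / pair[[2L]])
  lr <- stats::rnorm(nSites, logRatio, abs(logRatio) * selSD)
  cbind(A = f * gm * exp(lr / 2), B = f * gm * exp(-lr / 2))
}

realizeSiteGains <- function(config) {
  g <- lapply(config@bandGains, realizePair, nSites = config@nSites,
              gainSD = config@siteGainSD, selSD = config@siteSelectivitySD)
  rates <- realizePair(config@spikeRate[c("A", "B")], config@nSites,
                       config@siteGainSD, config@siteSelectivitySD)
  list(bandGains = g, spikeRates = rates)
}

#' Generate the multi-site LFP of one trial
#'
#' Synthesises a site x time LFP matrix as the sum of a 1/f background, a
#' 50 Hz line component and per-band band-limited Gaussian oscillations
#' whose epoch power equals the realised per-site gain of the presented
#' stimulus, multiplied in the test epoch by the repetition gain
#' (repetition trials) or the cross-adaptation gain (alternation trials).
#' Oscillations are created by band-pass filtering white noise (Butterworth,
#' forward-backward) and are stationary within each epoch; epoch onsets and
#' offsets are ramped over 20 ms. Each band's carrier mixes a component
#' shared across sites with a private per-site component according to
#' \code{sharedNoiseFraction}.
#'
#' @param trial one row of a trial table (list or single-row data frame).
#' @param config a \linkS4class{SimulationConfig}.
#' @param siteGains realised per-site gains from the session (internal);
#'   defaults to the nominal gains replicated across sites.
#' @param bands band definition table matching \code{names(bandGains)}.
#' @return numeric matrix, sites x time samples.
#' @export
generateLFP <- function(trial, config, siteGains = NULL,
                        bands = defaultBands()) {
  if (is.null(siteGains)) {
    siteGains <- lapply(config@bandGains, function(pair)
      matrix(rep(pair, each = config@nSites), ncol = 2L,
             dimnames = list(NULL, c("A", "B"))))
  }
  fs <- config@samplingRate
  msToSamp <- function(ms) round(ms * fs / 1000)
  nT <- msToSamp(config@preStim + 2 * config@stimDuration +
                 config@isi + config@postStim)
  nS <- config@nSites
  stimLen <- msToSamp(config@stimDuration)
  adOn <- msToSamp(config@preStim) + 1L
  teOn <- msToSamp(config@preStim + config@stimDuration + config@isi) + 1L
  ramp <- msToSamp(20)
  envA <- epochEnvelope(nT, adOn, stimLen, ramp)
  envT <- epochEnvelope(nT, teOn, stimLen, ramp)

  out <- matrix(0, nS, nT)
  for (s in seq_len(nS)) {
    if (config@backgroundAmplitude > 0)
      out[s, ] <- out[s, ] + config@backgroundAmplitude *
        pinkNoise(nT, config@noiseExponent, fs)
    if (config@lineNoiseAmplitude > 0)
      out[s, ] <- out[s, ] + config@lineNoiseAmplitude *
        cos(2 * pi * 50 * seq_len(nT) / fs + stats::runif(1L, 0, 2 * pi))
  }

  adaptGain <- if (isRepetition(trial$sequence_type))
    config@repetitionGain else config@crossAdaptationGain
  sh <- config@sharedNoiseFraction
  for (b in seq_len(nrow(bands))) {
    nm <- bands$name[b]
    gains <- siteGains[[nm]]
    if (is.null(gains)) next
    shared <- if (sh > 0) bandCarrier(nT, bands$lo[b], bands$hi[b], fs)
              else numeric(nT)
    for (s in seq_len(nS)) {
      gA <- gains[s, trial$adapter_stim]
      gT <- gains[s, trial$test_stim] * adaptGain[[nm]]
      if (gA == 0 && gT == 0) next
      carrier <- sqrt(sh) * shared +
        sqrt(1 - sh) * bandCarrier(nT, bands$lo[b], bands$hi[b], fs)
      out[s, ] <- out[s, ] + carrier * (sqrt(gA) * envA + sqrt(gT) * envT)
    }
  }
  out
}

#' Generate per-epoch multi-unit spike counts for one trial
#'
#' Draws Poisson spike counts per site for the adapter and test epochs,
#' with rate \code{lambda(stimulus, site) * window}; in repetition trials
#' the test-epoch rate is multiplied by \code{spikeAdaptationFactor}.
#' The counting window is the early analysis window (250 ms by default).
#'
#' @param trial one row of a trial table.
#' @param config a \linkS4class{SimulationConfig}.
#' @param siteRates realised per-site rate matrix (sites x 2, columns A, B);
#'   defaults to the nominal rates.
#' @param windowS counting window length in seconds.
#' @return integer matrix, sites x 2 (columns \code{adapter}, \code{test}).
#' @export
generateSpikes <- function(trial, config, siteRates = NULL, windowS = 0.25) {
  if (is.null(siteRates))
    siteRates <- matrix(rep(config@spikeRate[c("A", "B")],
                            each = config@nSites), ncol = 2L,
                        dimnames = list(NULL, c("A", "B")))
  if (any(siteRates < 0) || any(!is.finite(siteRates)))
    stop("spike rates must be finite and non-negative")
  lamA <- siteRates[, trial$adapter_stim] * windowS
  lamT <- siteRates[, trial$test_stim] * windowS
  if (isRepetition(trial$sequence_type))
    lamT <- lamT * config@spikeAdaptationFactor
  cbind(adapter = stats::rpois(config@nSites, lamA),
        test = stats::rpois(config@nSites, lamT))
}

#' Simulate a full adaptation-paradigm session
#'
#' Generates one penetration: trial table, per-trial multi-site LFP and
#' per-epoch spike counts, fully reproducible from the configuration seed.
#' Per-site selectivity (band gains and spike rates) is drawn once per
#' session around the nominal values, so sites carry partially independent
#' stimulus information.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param bands band definition table; defaults to \code{\link{defaultBands}}.
#' @return a \linkS4class{SessionRecording}.
#' @examples
#' cfg <- simulationConfig(nSites = 4, nTrialsPerSequence = 4,
#'                         abortProb = 0, seed = 11)
#' ses <- simulateSession(cfg)
#' ses
#' @export
simulateSession <- function(config, bands = defaultBands()) {
  stopifnot(methods::is(config, "SimulationConfig"))
  methods::validObject(config)
  validateBands(bands)
  withSeed(config@seed, {
    realized <- realizeSiteGains(config)
    trials <- generateTrialTableImpl(config)
    fs <- config@samplingRate
    nT <- round((config@preStim + 2 * config@stimDuration + config@isi +
                 config@postStim) * fs / 1000)
    n <- nrow(trials)
    lfp <- array(0, dim = c(n, config@nSites, nT))
    spikes <- array(0L, dim = c(n, config@nSites, 2L),
                    dimnames = list(NULL, NULL, c("adapter", "test")))
    for (i in seq_len(n)) {
      tr <- trials[i, ]
      lfp[i, , ] <- generateLFP(tr, config, realized$bandGains, bands)
      spikes[i, , ] <- generateSpikes(tr, config, realized$spikeRates)
    }
    methods::new("SessionRecording",
      lfp = lfp, spikes = spikes, trials = trials,
      samplingRate = fs, siteSpacing = 100,
      inputRange = config@inputRange,
      onsets = c(adapter = config@preStim,
                 test = config@preStim + config@stimDuration + config@isi),
      groundTruth = list(config = config, realized = realized))
  })
}

#' Simulate several penetrations
#'
#' Replicates \code{\link{simulateSession}} with per-penetration seeds
#' derived deterministically from one master seed, so penetrations differ
#' in their realised site selectivity and noise but the whole set is
#' reproducible.
#'
#' @param n number of penetrations.
#' @param config template \linkS4class{SimulationConfig}.
#' @param seed master seed (defaults to the config seed).
#' @param bands band definition table.
#' @return list of \linkS4class{SessionRecording} objects.
#' @export
simulatePenetrations <- function(n, config, seed = config@seed,
                                 bands = defaultBands()) {
  seeds <- deriveSeeds(seed, n)
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg@seed <- seeds[i]
    simulateSession(cfg, bands)
  })
}
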