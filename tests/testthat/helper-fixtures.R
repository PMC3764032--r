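## Small reusable fixtures, all generated in code.

## A fast single-band configuration for decoding tests.
tinyConfig <- function(nSites = 6L, nTrialsPerSequence = 12L, seed = 42L,
                       abortProb = 0, ...) {
  simulationConfig(nSites = nSites, nTrialsPerSequence = nTrialsPerSequence,
                   abortProb = abortProb, seed = seed, ...)
}

alphaOnlyBands <- function() data.frame(name = "alpha", lo = 8, hi = 12,
                                        stringsAsFactors = FALSE)

## Hand-built SessionRecording with arbitrary LFP content.
manualSession <- function(lfp, trials, fs = 1000,
                          inputRange = c(-500, 500),
                          onsets = c(adapter = 500, test = 1500),
                          spikes = NULL) {
  methods::new("SessionRecording", lfp = lfp, spikes = spikes,
               trials = trials, samplingRate = fs, siteSpacing = 100,
               inputRange = inputRange, onsets = onsets,
               groundTruth = list())
}

manualTrials <- function(types, aborted = rep(FALSE, length(types))) {
  data.frame(trial_id = seq_along(types), sequence_type = types,
             adapter_stim = substr(types, 1, 1),
             test_stim = substr(types, 2, 2),
             aborted = aborted, stringsAsFactors = FALSE)
}

## Gaussian feature set with known per-site class separation, wrapped as
## the feats/condition pair used by decodeCondition.
gaussianCondition <- function(nPerClass, nSitesG, delta, seed) {
  withr_seed <- function(s, code) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(s); code
  }
  withr_seed(seed, {
    xa <- matrix(rnorm(nPerClass * nSitesG, delta), nPerClass)
    xb <- matrix(rnorm(nPerClass * nSitesG, -delta), nPerClass)
    feats <- list(test = rbind(xa, xb))
    cond <- list(condition = "toy", subDatasets = list(
      list(epoch = "test", A = seq_len(nPerClass),
           B = nPerClass + seq_len(nPerClass))))
    list(feats = feats, cond = cond)
  })
}
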