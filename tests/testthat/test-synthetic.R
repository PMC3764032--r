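test_that("trial tables meet quotas and the sequencing constraint", {
  ## 8-trial toy table: 2 per sequence type
  tt8 <- adaptdecode:::withSeed(5L, adaptdecode:::generateTrialTableImpl(
    tinyConfig(seed = 5L), quota = rep(2L, 4L)))
  expect_equal(nrow(tt8), 8L)
  expect_equal(unname(table(tt8$sequence_type)[c("AA", "BB", "AB", "BA")]),
               rep(2L, 4L), ignore_attr = TRUE)
  expect_true(all(tt8$adapter_stim[-1L] != tt8$test_stim[-8L]))
  cfg <- tinyConfig(nTrialsPerSequence = 4L, seed = 5L)
  tt <- generateTrialTable(cfg)
  expect_equal(unname(table(tt$sequence_type[!tt$aborted])[c("AA", "BB", "AB", "BA")]),
               rep(4L, 4L), ignore_attr = TRUE)
  cfgAb <- tinyConfig(nTrialsPerSequence = 50L, seed = 9L, abortProb = 0.1)
  tt <- generateTrialTable(cfgAb)
  lastPresented <- ifelse(tt$aborted, tt$adapter_stim, tt$test_stim)
  expect_true(all(tt$adapter_stim[-1L] != lastPresented[-nrow(tt)]))
})

test_that("trial tables are deterministic and balanced at scale", {
  cfg <- tinyConfig(nTrialsPerSequence = 2500L, seed = 3L)
  tt1 <- generateTrialTable(cfg)
  tt2 <- generateTrialTable(cfg)
  expect_identical(tt1, tt2)
  ## per-type frequency of 1/4 each, within binomial 99% bounds
  n <- nrow(tt1)
  freqs <- table(tt1$sequence_type) / n
  bound <- 2.58 * sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(freqs - 0.25) <= bound))
})

test_that("unsatisfiable sequencing constraints are rejected", {
  cfg <- tinyConfig(seed = 1L, abortProb = 0)
  ## a quota of AA trials alone cannot satisfy the
  ## adapter-differs-from-last-stimulus rule (after AA the next adapter
  ## would have to be B)
  expect_error(
    adaptdecode:::withSeed(1L, adaptdecode:::generateTrialTableImpl(
      cfg, quota = c(4L, 0L, 0L, 0L))),
    "unsatisfiable")
  ## but AA+BB alone can (strict alternation)
  tt <- adaptdecode:::withSeed(1L, adaptdecode:::generateTrialTableImpl(
    cfg, quota = c(4L, 4L, 0L, 0L)))
  expect_equal(sort(unique(tt$sequence_type)), c("AA", "BB"))
})

test_that("degenerate generator settings give an all-zero trace", {
  zeroGains <- list(alpha = c(A = 0, B = 0))
  cfg <- simulationConfig(nSites = 2, nTrialsPerSequence = 4, abortProb = 0,
                          bandGains = zeroGains,
                          repetitionGain = c(alpha = 1),
                          crossAdaptationGain = c(alpha = 1),
                          backgroundAmplitude = 0, lineNoiseAmplitude = 0,
                          seed = 1)
  tr <- list(sequence_type = "AA", adapter_stim = "A", test_stim = "A")
  x <- generateLFP(tr, cfg, bands = alphaOnlyBands())
  expect_true(all(x == 0))
})

test_that("epoch band power tracks the configured gains (periodogram oracle)", {
  ## alpha selectivity A:B = 4, negligible background
  cfg <- simulationConfig(
    nSites = 1, nTrialsPerSequence = 4, abortProb = 0,
    bandGains = list(alpha = c(A = 0.8, B = 0.2)),
    repetitionGain = c(alpha = 1), crossAdaptationGain = c(alpha = 1),
    backgroundAmplitude = 0.02, lineNoiseAmplitude = 0,
    siteGainSD = 0, siteSelectivitySD = 0, sharedNoiseFraction = 0,
    seed = 8)
  bands <- alphaOnlyBands()
  fs <- 1000
  trA <- list(sequence_type = "AB", adapter_stim = "A", test_stim = "B")
  trB <- list(sequence_type = "BA", adapter_stim = "B", test_stim = "A")
  set.seed(21)
  pA <- replicate(100, {
    x <- generateLFP(trA, cfg, bands = bands)[1, ]
    welchBandPower(x[601:950], fs, bands)   # adapter steady state
  })
  pB <- replicate(100, {
    x <- generateLFP(trB, cfg, bands = bands)[1, ]
    welchBandPower(x[601:950], fs, bands)
  })
  ratio <- mean(pA) / mean(pB)
  expect_gt(ratio, 4 * 0.8)
  expect_lt(ratio, 4 * 1.2)
})

test_that("repetition suppression halves test-epoch high-gamma power", {
  cfg <- simulationConfig(
    nSites = 1, nTrialsPerSequence = 4, abortProb = 0,
    bandGains = list(high_gamma = c(A = 0.5, B = 0.5)),
    repetitionGain = c(high_gamma = 0.5),
    crossAdaptationGain = c(high_gamma = 1),
    backgroundAmplitude = 0.02, lineNoiseAmplitude = 0,
    siteGainSD = 0, siteSelectivitySD = 0, sharedNoiseFraction = 0,
    seed = 8)
  bands <- data.frame(name = "high_gamma", lo = 101, hi = 170)
  tr <- list(sequence_type = "AA", adapter_stim = "A", test_stim = "A")
  set.seed(22)
  r <- replicate(120, {
    x <- generateLFP(tr, cfg, bands = bands)[1, ]
    c(ad = welchBandPower(x[601:950], 1000, bands),
      te = welchBandPower(x[1601:1950], 1000, bands))
  })
  ratio <- mean(r["te", ]) / mean(r["ad", ])
  expect_gt(ratio, 0.5 * 0.8)
  expect_lt(ratio, 0.5 * 1.2)
})

test_that("epoch band power scales linearly with the configured gain", {
  mk <- function(g) simulationConfig(
    nSites = 1, nTrialsPerSequence = 4, abortProb = 0,
    bandGains = list(beta = c(A = g, B = g)),
    repetitionGain = c(beta = 1), crossAdaptationGain = c(beta = 1),
    backgroundAmplitude = 0, lineNoiseAmplitude = 0,
    siteGainSD = 0, siteSelectivitySD = 0, sharedNoiseFraction = 0,
    seed = 8)
  bands <- data.frame(name = "beta", lo = 13, hi = 30)
  tr <- list(sequence_type = "AB", adapter_stim = "A", test_stim = "B")
  set.seed(23)
  p1 <- mean(replicate(100, welchBandPower(
    generateLFP(tr, mk(0.2), bands = bands)[1, 601:950], 1000, bands)))
  set.seed(23)
  p4 <- mean(replicate(100, welchBandPower(
    generateLFP(tr, mk(0.8), bands = bands)[1, 601:950], 1000, bands)))
  expect_gt(p4 / p1, 4 * 0.9)
  expect_lt(p4 / p1, 4 * 1.1)
})

test_that("spike counts follow the configured Poisson law", {
  cfg <- simulationConfig(nSites = 100, nTrialsPerSequence = 4,
                          spikeRate = c(A = 80, B = 80),
                          spikeAdaptationFactor = 1, seed = 1)
  tr <- list(sequence_type = "AB", adapter_stim = "A", test_stim = "B")
  rates <- matrix(80, 100, 2, dimnames = list(NULL, c("A", "B")))
  set.seed(31)
  counts <- replicate(100, generateSpikes(tr, cfg, rates)[, "adapter"])
  expect_lt(abs(mean(counts) - 20) / 20, 0.02)   # lambda * 0.25 s = 20

  ## zero rate gives zero counts
  zero <- generateSpikes(tr, cfg, rates * 0)
  expect_true(all(zero == 0))
  expect_error(generateSpikes(tr, cfg, rates - 100), "non-negative")

  ## adaptation factor 1: adapter and test counts share one law
  trAA <- list(sequence_type = "AA", adapter_stim = "A", test_stim = "A")
  set.seed(32)
  draws <- replicate(20, generateSpikes(trAA, cfg, rates))
  expect_gt(stats::wilcox.test(draws[, 1, ], draws[, 2, ])$p.value, 0.01)
})

test_that("unit adaptation gains make adapter and test epochs exchangeable", {
  cfg <- simulationConfig(
    nSites = 2, nTrialsPerSequence = 12, abortProb = 0,
    bandGains = list(alpha = c(A = 0.5, B = 0.25)),
    repetitionGain = c(alpha = 1), crossAdaptationGain = c(alpha = 1),
    lineNoiseAmplitude = 0, seed = 77)
  ses <- simulateSession(cfg, alphaOnlyBands())
  bpt <- bandPower(ses, alphaOnlyBands())
  ## compare adapter vs test power for matched stimulus, AA/BB trials only
  rep_rows <- which(ses@trials$sequence_type %in% c("AA", "BB") &
                      !ses@trials$aborted)
  ad <- as.vector(powerArray(bpt)[rep_rows, , 1, "adapter"])
  te <- as.vector(powerArray(bpt)[rep_rows, , 1, "test"])
  expect_gt(stats::wilcox.test(ad, te, paired = TRUE)$p.value, 0.01)
})

test_that("sessions are byte-identical under a fixed seed", {
  cfg <- tinyConfig(nSites = 2L, nTrialsPerSequence = 4L, seed = 13L)
  s1 <- simulateSession(cfg, alphaOnlyBands())
  s2 <- simulateSession(cfg, alphaOnlyBands())
  expect_identical(lfpData(s1), lfpData(s2))
  expect_identical(spikeCounts(s1), spikeCounts(s2))
  expect_identical(trialTable(s1), trialTable(s2))
})

test_that("session containers round-trip through disk", {
  cfg <- tinyConfig(nSites = 2L, nTrialsPerSequence = 4L, seed = 14L)
  ses <- simulateSession(cfg, alphaOnlyBands())
  dir <- tempfile("session")
  writeSession(ses, dir)
  back <- readSession(dir)
  expect_equal(lfpData(back), lfpData(ses))
  expect_equal(unname(spikeCounts(back)[, , "test"]),
               unname(spikeCounts(ses)[, , "test"] * 1.0))
  expect_equal(trialTable(back), trialTable(ses))
  expect_equal(samplingRate(back), samplingRate(ses))
  unlink(dir, recursive = TRUE)
})
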