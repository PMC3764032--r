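test_that("condition construction enumerates the four two-class designs", {
  tt <- manualTrials(rep(c("AA", "BB", "AB", "BA"), each = 2))
  conds <- buildConditions(tt)
  expect_named(conds, c("Adapter", "Test_rep", "Test_alt",
                        "Test_sameAdapter"))
  ## Adapter: (AA vs BB) and (AB vs BA), 2 + 2 trials each
  expect_length(conds$Adapter$subDatasets, 2L)
  expect_equal(lengths(conds$Adapter$subDatasets[[1]][c("A", "B")]),
               c(A = 2L, B = 2L))
  expect_equal(lengths(conds$Adapter$subDatasets[[2]][c("A", "B")]),
               c(A = 2L, B = 2L))
  ## Test_rep: AA tests (class A) vs BB tests (class B)
  expect_equal(conds$Test_rep$subDatasets[[1]]$A, which(tt$sequence_type == "AA"))
  expect_equal(conds$Test_rep$subDatasets[[1]]$epoch, "test")
  ## Test_alt labels follow the test stimulus: AB tests are class B
  expect_equal(conds$Test_alt$subDatasets[[1]]$B, which(tt$sequence_type == "AB"))
  expect_equal(conds$Test_alt$subDatasets[[1]]$A, which(tt$sequence_type == "BA"))
  ## Test_sameAdapter: AA vs AB (adapter A), BA vs BB (adapter B)
  expect_equal(conds$Test_sameAdapter$subDatasets[[1]]$B,
               which(tt$sequence_type == "AB"))
  expect_equal(conds$Test_sameAdapter$subDatasets[[2]]$B,
               which(tt$sequence_type == "BB"))
  ## a missing sequence type empties a class
  expect_error(buildConditions(tt[tt$sequence_type != "AB", ]), "empty class")
})

test_that("trial-count equalisation floors the minimum to an even number", {
  mk <- function(sizes) {
    list(c1 = list(condition = "c1", subDatasets = list(
      list(epoch = "test", A = seq_len(sizes[1]), B = seq_len(sizes[2])))),
      c2 = list(condition = "c2", subDatasets = list(
        list(epoch = "test", A = seq_len(sizes[3]), B = seq_len(sizes[4])))))
  }
  expect_equal(equalizeNTot(mk(c(120, 118, 117, 119))), 116L)
  expect_equal(equalizeNTot(mk(rep(112, 4))), 112L)
  expect_error(equalizeNTot(mk(c(120, 118, 3, 119))), "rejected")
})

test_that("half splits are disjoint, balanced and seed-reproducible", {
  ids <- 1:20
  set.seed(1)
  sp <- splitHalf(ids, 8L)
  expect_length(sp$train, 4L)
  expect_length(sp$test, 4L)
  expect_length(intersect(sp$train, sp$test), 0L)
  set.seed(7); a <- splitHalf(ids, 8L)
  set.seed(7); b <- splitHalf(ids, 8L)
  expect_identical(a, b)
  expect_error(splitHalf(1:3, 8L), "fewer")
})

test_that("train-set membership frequency matches the sampling law", {
  ## each of M trials enters training with probability (nTot/M) * 1/2
  M <- 20L; nTot <- 12L
  set.seed(8)
  hits <- integer(M)
  B <- 1000
  for (i in seq_len(B)) {
    sp <- splitHalf(seq_len(M), nTot)
    hits[sp$train] <- hits[sp$train] + 1L
  }
  pExp <- (nTot / M) / 2
  bound <- 3.3 * sqrt(pExp * (1 - pExp) / B)
  expect_true(all(abs(hits / B - pExp) <= bound))
})

test_that("z-normalisation uses training statistics only", {
  z <- zNormalize(matrix(c(1, 3)), matrix(2))
  expect_equal(as.vector(z$train), c(-1, 1) / stats::sd(c(1, 3)) * 1)
  expect_equal(unname(colMeans(z$train)), 0)
  expect_equal(unname(apply(z$train, 2, sd)), 1)
  expect_equal(as.vector(z$test), 0)       # test value at the train mean
  ## applying the transform twice is not a no-op on non-standardised data
  z2 <- zNormalize(z$train * 5 + 2, z$test * 5 + 2)
  expect_false(isTRUE(all.equal(z2$train, z$train * 5 + 2)))
  ## constant features are silenced
  zc <- zNormalize(matrix(c(4, 4)), matrix(9))
  expect_equal(as.vector(zc$train), c(0, 0))
  expect_equal(as.vector(zc$test), 0)
  expect_equal(zc$constantFeatures, 1L)
})

test_that("the linear SVM recovers the symmetric 1-D boundary", {
  clf <- trainLinearSVM(matrix(c(-1, -1, 1, 1), ncol = 1),
                        c("A", "A", "B", "B"))
  expect_equal(clf$b, 0, tolerance = 1e-8)
  expect_equal(svmAccuracy(clf, matrix(c(-2, 2), ncol = 1), c("A", "B")), 1)
  ## separable clouds: hard-margin behaviour, perfect training accuracy
  set.seed(3)
  x <- rbind(matrix(rnorm(20, -3), ncol = 2), matrix(rnorm(20, 3), ncol = 2))
  y <- rep(c("A", "B"), each = 10)
  clf2 <- trainLinearSVM(x, y)
  expect_equal(svmAccuracy(clf2, x, y), 1)
  expect_error(trainLinearSVM(x, rep("A", 20)), "both classes")
})

test_that("SVM weights match the exact QP active-set oracle", {
  set.seed(5)
  for (trial in 1:8) {
    x <- matrix(rnorm(12, sd = 2), ncol = 2)
    y <- rep(c("A", "B"), each = 3)
    ref <- svmQPOracle(x, y, C = 1)
    expect_false(is.null(ref))
    clf <- trainLinearSVM(x, y, cost = 1, tolerance = 1e-12)
    expect_lt(max(abs(clf$w - ref$w)), 1e-6)
    ## the offset is only pinned down when a support vector sits strictly
    ## inside the box (otherwise any b in an interval is optimal)
    if (any(ref$alpha > 1e-8 & ref$alpha < 1 - 1e-8))
      expect_lt(abs(clf$b - ref$b), 1e-6)
  }
})

test_that("boundary ties score half credit", {
  clf <- list(w = c(1, 0), b = 0)
  x <- rbind(c(0, 5), c(1, 0), c(-1, 0))
  expect_equal(svmAccuracy(clf, x, c("A", "A", "B")), (0.5 + 1 + 1) / 3)
})

test_that("decoding accuracy tracks the signal from chance to ceiling", {
  null <- gaussianCondition(60, 4, 0, seed = 21)
  d0 <- decodeCondition(null$feats, null$cond, nTot = 40, nRep = 60,
                        seed = 2)
  expect_lt(abs(d0$mean - 50), 6)
  strong <- gaussianCondition(60, 4, 4, seed = 22)
  d1 <- decodeCondition(strong$feats, strong$cond, nTot = 40, nRep = 30,
                        seed = 2)
  expect_gt(d1$mean, 99)
})

test_that("decoder approaches the Bayes rate of a known Gaussian law", {
  ## per-site means +-delta, unit variance, K independent sites:
  ## Bayes accuracy = Phi(delta * sqrt(K))
  K <- 4L
  delta <- qnorm(0.75) / sqrt(K)
  g <- gaussianCondition(220, K, delta, seed = 23)
  d <- decodeCondition(g$feats, g$cond, nTot = 200, nRep = 150, seed = 3)
  expect_lt(abs(d$mean - 75), 5)
})

test_that("label shuffling centres accuracy on chance", {
  strong <- gaussianCondition(60, 4, 2, seed = 24)
  sh <- shuffleControl(strong$feats, strong$cond, nTot = 40, nPerm = 300,
                       seed = 4)
  mcSD <- sd(sh$perRep) / sqrt(sh$nRep)
  expect_lt(abs(sh$mean - 50), 3 * mcSD + 1)
  ## permutation spread shrinks roughly like 1/sqrt(test-set size)
  g2 <- gaussianCondition(160, 4, 2, seed = 25)
  shBig <- shuffleControl(g2$feats, g2$cond, nTot = 160, nPerm = 300,
                          seed = 5)
  expect_lt(sd(shBig$perRep), sd(sh$perRep))
})

test_that("accuracy is exactly invariant to per-site affine rescaling", {
  g <- gaussianCondition(40, 5, 0.3, seed = 26)
  scaled <- g
  sc <- c(3, -0.5, 10, 0.01, 7)
  off <- c(-2, 5, 0, 100, -30)
  scaled$feats$test <- sweep(sweep(g$feats$test, 2, sc, "*"), 2, off, "+")
  d1 <- decodeCondition(g$feats, g$cond, nTot = 30, nRep = 40, seed = 6)
  d2 <- decodeCondition(scaled$feats, scaled$cond, nTot = 30, nRep = 40,
                        seed = 6)
  expect_identical(d1$perRep, d2$perRep)
})

test_that("paired sub-scores are averaged after an equality check", {
  same <- averagePairedScores(c(55, 60, 62), c(55, 60, 62))
  expect_equal(same$average, c(55, 60, 62))
  expect_equal(same$p, 1)
  expect_equal(averagePairedScores(c(55, 60), c(57, 62))$average, c(56, 61))
  expect_error(averagePairedScores(1:3, 1:4), "equal length")
  ## a planted shift is detected with high power at n = 20, sd = 3
  set.seed(9)
  s1 <- rnorm(20, 60, 3)
  s2 <- s1 + 5
  expect_warning(out <- averagePairedScores(s1, s2), "differ")
  expect_true(out$differs)
})

test_that("site subsampling keeps round(n/3) evenly spaced sites", {
  expect_length(selectSites(15), 5L)
  expect_length(selectSites(16), 5L)
  expect_equal(selectSites(16), c(1, 5, 8, 12, 16))
  expect_error(selectSites(2), "at least 3")
  set.seed(2)
  r <- selectSites(16, method = "random", seed = 3)
  expect_length(r, 5L)
  expect_identical(r, selectSites(16, method = "random", seed = 3))
})

test_that("spike-count features support the same decoding pipeline", {
  mkSpikes <- function(lamA, lamB, n, K, seed) {
    set.seed(seed)
    feats <- list(test = rbind(
      matrix(rpois(n * K, lamA), n),
      matrix(rpois(n * K, lamB), n)) * 1.0)
    cond <- list(condition = "mua", subDatasets = list(
      list(epoch = "test", A = seq_len(n), B = n + seq_len(n))))
    list(feats = feats, cond = cond)
  }
  ## 2:1 rate ratio is decodable above chance
  g <- mkSpikes(8, 4, 60, 6, seed = 31)
  d <- decodeCondition(g$feats, g$cond, nTot = 40, nRep = 50, seed = 7)
  nTests <- 40 * 50
  expect_gt(d$mean / 100, 0.5 + qnorm(0.99) * sqrt(0.25 / nTests))
  ## equal rates decode at chance on average over independent pools
  ## (any one finite pool carries an accidental class difference that
  ## resampled splits partially share, so single-pool accuracy scatters)
  m0 <- sapply(33:37, function(s) {
    g0 <- mkSpikes(6, 6, 60, 6, seed = s)
    decodeCondition(g0$feats, g0$cond, nTot = 40, nRep = 40, seed = 7)$mean
  })
  expect_lt(abs(mean(m0) - 50), 4)
})
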