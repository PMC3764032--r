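#' @include AllClasses.R spectral.R
NULL

conditionNames <- function() c("Adapter", "Test_rep", "Test_alt",
                               "Test_sameAdapter")

#' Build the four two-class stimulus conditions
#'
#' Partitions the (already cleaned) trials of one penetration into the
#' four decoding conditions, each a set of one or two two-class
#' sub-datasets with class labels A and B:
#' \itemize{
#'   \item \code{Adapter}: adapter epochs, scored separately for
#'     repetition trials (AA vs BB) and alternation trials (AB vs BA);
#'     the class label is the adapter stimulus.
#'   \item \code{Test_rep}: test epochs of AA vs BB.
#'   \item \code{Test_alt}: test epochs of alternation trials, labelled by
#'     the test stimulus (BA is class A, AB is class B).
#'   \item \code{Test_sameAdapter}: test stimuli following the same
#'     adapter, scored separately for AA vs AB and BB vs BA; the class
#'     label is the test stimulus within the fixed adapter.
#' }
#'
#' @param trials trial table with rejected and aborted trials already
#'   excluded.
#' @return named list of condition objects, each with elements
#'   \code{condition} and \code{subDatasets} (lists with \code{epoch},
#'   \code{A}, \code{B} index vectors into the trial table rows).
#' @examples
#' tt <- generateTrialTable(simulationConfig(nTrialsPerSequence = 4,
#'                                           abortProb = 0, seed = 2))
#' names(buildConditions(tt[!tt$aborted, ]))
#' @export
buildConditions <- function(trials) {
  rows <- function(type) which(trials$sequence_type == type)
  aa <- rows("AA"); bb <- rows("BB"); ab <- rows("AB"); ba <- rows("BA")
  conds <- list(
    Adapter = list(condition = "Adapter", subDatasets = list(
      list(epoch = "adapter", A = aa, B = bb),
      list(epoch = "adapter", A = ab, B = ba))),
    Test_rep = list(condition = "Test_rep", subDatasets = list(
      list(epoch = "test", A = aa, B = bb))),
    Test_alt = list(condition = "Test_alt", subDatasets = list(
      list(epoch = "test", A = ba, B = ab))),
    Test_sameAdapter = list(condition = "Test_sameAdapter", subDatasets = list(
      list(epoch = "test", A = aa, B = ab),
      list(epoch = "test", A = ba, B = bb)))
  )
  for (cn in names(conds))
    for (sd in conds[[cn]]$subDatasets)
      if (!length(sd$A) || !length(sd$B))
        stop(sprintf("condition %s has an empty class; penetration rejected",
                     cn))
  conds
}

#' Equalised per-class trial count
#'
#' The number of trials per stimulus entering every classifier,
#' \code{N_tot}: the largest even integer not exceeding the smallest
#' per-class trial count over all sub-datasets of all four conditions.
#' Using one shared \code{N_tot} makes accuracies comparable across
#' conditions; the even constraint guarantees an exact half/half
#' train/test split.
#'
#' @param conditions output of \code{\link{buildConditions}}.
#' @return integer \code{N_tot}.
#' @examples
#' \dontrun{equalizeNTot(buildConditions(trials))}
#' @export
equalizeNTot <- function(conditions) {
  counts <- unlist(lapply(conditions, function(cond)
    lapply(cond$subDatasets, function(sd) c(length(sd$A), length(sd$B)))))
  nTot <- 2L * (min(counts) %/% 2L)
  if (nTot < 4L)
    stop("fewer than 4 usable trials per class; penetration rejected")
  as.integer(nTot)
}

#' Draw a balanced half/half train/test split for one class
#'
#' Samples \code{nTot} trials of the class without replacement from its
#' pool, assigns the first half to training and the second half to
#' testing. Train and test sets are disjoint by construction.
#'
#' @param ids trial indices of one class.
#' @param nTot equalised per-class trial count (even).
#' @return list with integer vectors \code{train} and \code{test}.
#' @export
splitHalf <- function(ids, nTot) {
  if (length(ids) < nTot)
    stop("class has fewer trials than N_tot")
  pick <- sample(ids, nTot)
  list(train = pick[seq_len(nTot / 2L)],
       test = pick[(nTot / 2L + 1L):nTot])
}

#' z-normalise features with training statistics
#'
#' Standardises every feature (site) by the mean and standard deviation
#' computed across both classes of the training trials only; test
#' features are transformed with the training statistics. A feature with
#' zero training standard deviation carries no information and is set to
#' zero in both sets (and reported).
#'
#' @param train,test numeric matrices, trials x features.
#' @return list with \code{train}, \code{test} and \code{constantFeatures}
#'   (indices of zero-variance training features).
#' @export
zNormalize <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  const <- which(sdv == 0 | !is.finite(sdv))
  sdv[const] <- 1
  tr <- sweep(sweep(train, 2L, mu), 2L, sdv, "/")
  te <- sweep(sweep(test, 2L, mu), 2L, sdv, "/")
  if (length(const)) {
    tr[, const] <- 0
    te[, const] <- 0
  }
  list(train = tr, test = te, constantFeatures = const)
}

#' Train a linear support vector machine
#'
#' Fits a two-class soft-margin linear SVM with fixed unit cost
#' (reducing to the maximum-margin rule on separable data). The fit is
#' deterministic given the data. Returns the hyperplane explicitly so
#' that the decision rule \code{w . x + b} can be inspected and compared
#' against quadratic-programming references.
#'
#' @param x numeric matrix, trials x features (normalised).
#' @param y factor or character vector of class labels A/B.
#' @param cost soft-margin cost parameter.
#' @param tolerance optimiser termination tolerance.
#' @return list with elements \code{w} (weight vector), \code{b}
#'   (offset; decision value \code{w . x + b} is positive for class A)
#'   and \code{model} (the underlying fit).
#' @export
trainLinearSVM <- function(x, y, cost = 1, tolerance = 1e-3) {
  y <- factor(as.character(y), levels = c("A", "B"))
  if (nlevels(droplevels(y)) < 2L)
    stop("both classes must be present in the training set")
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
                    tolerance = tolerance)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  ## e1071 assigns +1 to the first class seen in the data, not to the
  ## first factor level; flip so that positive decision values mean "A".
  if (fit$labels[1L] != 1L) { w <- -w; b <- -b }
  list(w = w, b = b, model = fit)
}

#' Classification accuracy of a linear decision rule
#'
#' Fraction of test trials on the correct side of the hyperplane; a
#' decision value exactly on the boundary counts as half correct
#' (unbiased tie handling for a measure-zero event).
#'
#' @param clf output of \code{\link{trainLinearSVM}}.
#' @param x test feature matrix.
#' @param y true labels.
#' @return accuracy in [0, 1].
#' @export
svmAccuracy <- function(clf, x, y) {
  d <- drop(x %*% clf$w) + clf$b
  correct <- ifelse(d == 0, 0.5, (d > 0) == (as.character(y) == "A"))
  mean(correct)
}

## One train/test repetition on one sub-dataset. Returns accuracy in [0,1].
subDatasetAccuracy <- function(feats, sd, nTot, shuffle, cost) {
  A <- sd$A; B <- sd$B
  if (shuffle) {
    pool <- c(A, B)
    lab <- sample(rep(c("A", "B"), c(length(A), length(B))))
    A <- pool[lab == "A"]; B <- pool[lab == "B"]
  }
  spA <- splitHalf(A, nTot)
  spB <- splitHalf(B, nTot)
  xtr <- feats[[sd$epoch]][c(spA$train, spB$train), , drop = FALSE]
  xte <- feats[[sd$epoch]][c(spA$test, spB$test), , drop = FALSE]
  ytr <- rep(c("A", "B"), each = nTot / 2L)
  yte <- ytr
  z <- zNormalize(xtr, xte)
  clf <- trainLinearSVM(z$train, ytr, cost = cost)
  svmAccuracy(clf, z$test, yte)
}

#' Decode one condition by resampled cross-validation
#'
#' Trains and tests \code{nRep} linear-SVM classifiers for one condition,
#' each repetition drawing \code{nTot} trials per class afresh from the
#' full pool (resampled cross-validation), splitting them half/half into
#' train and test, z-normalising with training statistics and scoring on
#' the held-out half. For conditions with two sub-datasets the two
#' accuracies of a repetition are averaged with equal weight. Every
#' repetition uses a deterministically derived seed, so results are
#' reproducible and independent of evaluation order.
#'
#' @param feats named list of feature matrices (trials x sites), one per
#'   epoch used by the condition (\code{adapter} and/or \code{test}).
#' @param cond one condition object from \code{\link{buildConditions}}.
#' @param nTot equalised per-class trial count.
#' @param nRep number of classifier repetitions.
#' @param seed master seed of this decoding run.
#' @param shuffle if \code{TRUE}, class labels are randomly permuted
#'   across the trials of each sub-dataset before every split
#'   (label-shuffle null control).
#' @param cost SVM soft-margin cost.
#' @return list with \code{mean} (mean accuracy, \%), \code{perRep}
#'   (per-repetition accuracies, \%), \code{perSub} (per-sub-dataset mean
#'   accuracies, \%), \code{nTot} and \code{nRep}.
#' @export
decodeCondition <- function(feats, cond, nTot, nRep = 1000, seed = 1,
                            shuffle = FALSE, cost = 1) {
  for (sd in cond$subDatasets)
    if (length(sd$A) < nTot || length(sd$B) < nTot)
      stop("sub-dataset smaller than N_tot; equalisation violated")
  repSeeds <- deriveSeeds(seed, nRep)
  nSub <- length(cond$subDatasets)
  subAcc <- matrix(NA_real_, nRep, nSub)
  for (r in seq_len(nRep)) {
    withSeed(repSeeds[r], {
      for (k in seq_len(nSub))
        subAcc[r, k] <- subDatasetAccuracy(feats, cond$subDatasets[[k]],
                                           nTot, shuffle, cost)
    })
  }
  perRep <- rowMeans(subAcc) * 100
  list(mean = mean(perRep), perRep = perRep,
       perSub = colMeans(subAcc) * 100, nTot = nTot, nRep = nRep)
}

#' Label-shuffle null control
#'
#' Re-runs the full decoding pipeline of a condition with stimulus labels
#' randomly permuted across trials before each split. The expected mean
#' accuracy is 50\%; the permutation distribution provides the empirical
#' chance level.
#'
#' @inheritParams decodeCondition
#' @param nPerm number of label permutations (one classifier each).
#' @return list as in \code{\link{decodeCondition}}, where \code{perRep}
#'   is the permutation distribution.
#' @export
shuffleControl <- function(feats, cond, nTot, nPerm = 1000, seed = 1,
                           cost = 1) {
  decodeCondition(feats, cond, nTot, nRep = nPerm, seed = seed,
                  shuffle = TRUE, cost = cost)
}

#' Average paired scores after an equality check
#'
#' Averages two paired per-penetration score vectors (for example the
#' repetition- and alternation-trial sub-scores of the Adapter condition)
#' after testing, with a two-sided Wilcoxon matched-pairs test at a
#' Bonferroni-corrected level, that they do not differ. The average is
#' returned regardless; a warning is raised when the test rejects.
#'
#' @param scores1,scores2 paired numeric vectors (one entry per
#'   penetration).
#' @param alpha significance level of the equality check (default 0.025,
#'   Bonferroni-corrected for two subjects).
#' @return list with \code{average}, \code{p}, \code{statistic} and
#'   \code{differs}.
#' @export
averagePairedScores <- function(scores1, scores2, alpha = 0.025) {
  if (length(scores1) != length(scores2))
    stop("paired score vectors must have equal length")
  wt <- wilcoxonMatchedPairs(scores1, scores2)
  if (!is.na(wt$p.value) && wt$p.value < alpha)
    warning(sprintf(
      "paired scores differ (Wilcoxon p = %.3g < %.3g); averaging anyway",
      wt$p.value, alpha))
  list(average = (scores1 + scores2) / 2, p = wt$p.value,
       statistic = wt$statistic, differs = isTRUE(wt$p.value < alpha))
}

#' Select a reduced set of laminar sites
#'
#' Returns \code{round(nSites * fraction)} site indices, evenly spaced
#' along the probe by default (deterministic) or drawn at random with a
#' seed. Used for the reduced-site control that probes whether sites
#' carry independent stimulus information.
#'
#' @param nSites number of available sites (>= 3).
#' @param fraction fraction of sites to keep (default 1/3).
#' @param method \code{"even"} or \code{"random"}.
#' @param seed seed for random selection.
#' @return integer vector of site indices.
#' @examples
#' selectSites(16)  # 5 evenly spaced sites
#' @export
selectSites <- function(nSites, fraction = 1 / 3, method = c("even", "random"),
                        seed = 1) {
  method <- match.arg(method)
  if (nSites < 3L) stop("site subsampling requires at least 3 sites")
  k <- max(1L, round(nSites * fraction))
  if (method == "even") unique(round(seq(1L, nSites, length.out = k)))
  else withSeed(seed, sort(sample.int(nSites, k)))
}

#' Restrict a session to a subset of its sites
#'
#' @param session a \linkS4class{SessionRecording}.
#' @param fraction fraction of sites to keep.
#' @param method,seed see \code{\link{selectSites}}.
#' @return the reduced session.
#' @export
subsampleSites <- function(session, fraction = 1 / 3,
                           method = c("even", "random"), seed = 1) {
  idx <- selectSites(nSites(session), fraction, method, seed)
  session@lfp <- session@lfp[, idx, , drop = FALSE]
  if (!is.null(session@spikes))
    session@spikes <- session@spikes[, idx, , drop = FALSE]
  session
}

## Feature matrices per epoch for one band of a BandPowerTable.
bandFeatures <- function(bpt, band) {
  bi <- match(band, bpt@bands$name)
  if (is.na(bi)) stop(sprintf("unknown band '%s'", band))
  list(adapter = bpt@power[, , bi, "adapter"],
       test = bpt@power[, , bi, "test"])
}

## Feature matrices per epoch from spike counts.
muaFeatures <- function(session) {
  if (is.null(session@spikes)) stop("session has no spike counts")
  list(adapter = session@spikes[, , "adapter"] * 1.0,
       test = session@spikes[, , "test"] * 1.0)
}

#' Decode one penetration across bands and conditions
#'
#' End-to-end decoding of one session: optional notch filtering and
#' clipped/aborted-trial rejection, Morlet band power, condition
#' construction, trial-count equalisation (one shared \code{N_tot} across
#' all conditions and feature sets of the penetration, so accuracies are
#' comparable), then resampled cross-validated linear-SVM decoding for
#' every frequency band (and optionally spike counts, labelled
#' \code{MUA}) and every condition, with an optional label-shuffle
#' control.
#'
#' @param session a \linkS4class{SessionRecording}.
#' @param bands band definition table.
#' @param params a \code{\link{preprocessParams}} object.
#' @param nRep classifier repetitions per condition.
#' @param nShuffle label permutations for the shuffle control (0 = skip).
#' @param seed master seed.
#' @param penetration identifier recorded in the results.
#' @param mua if \code{TRUE} and spike counts are present, also decode
#'   spike-count features.
#' @param siteFraction if non-\code{NULL}, decode using only this
#'   fraction of evenly spaced sites (reduced-site control).
#' @param preprocess if \code{FALSE}, skip notch filtering and trial
#'   rejection (e.g. for already-clean input).
#' @param cost SVM soft-margin cost.
#' @return a \linkS4class{DecodingResult}.
#' @export
decodeSession <- function(session, bands = defaultBands(),
                          params = preprocessParams(), nRep = 1000,
                          nShuffle = 0, seed = 1, penetration = "pen1",
                          mua = TRUE, siteFraction = NULL,
                          preprocess = TRUE, cost = 1) {
  if (preprocess) {
    session <- notchFilterSession(session, params)
    session <- rejectClippedTrials(session, params)$session
  }
  if (!is.null(siteFraction))
    session <- subsampleSites(session, siteFraction)
  bpt <- bandPower(session, bands, params)
  conds <- buildConditions(bpt@trials)
  nTot <- equalizeNTot(conds)
  featSets <- stats::setNames(
    lapply(bands$name, function(b) bandFeatures(bpt, b)), bands$name)
  if (mua && !is.null(session@spikes))
    featSets$MUA <- muaFeatures(session)
  cells <- expand.grid(band = names(featSets), condition = conditionNames(),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cellSeeds <- matrix(deriveSeeds(seed, 2L * nrow(cells)), ncol = 2L)
  rows <- vector("list", nrow(cells))
  scores <- list()
  for (i in seq_len(nrow(cells))) {
    bd <- cells$band[i]; cn <- cells$condition[i]
    dec <- decodeCondition(featSets[[bd]], conds[[cn]], nTot, nRep,
                           seed = cellSeeds[i, 1L], cost = cost)
    shuf <- if (nShuffle > 0)
      shuffleControl(featSets[[bd]], conds[[cn]], nTot, nShuffle,
                     seed = cellSeeds[i, 2L], cost = cost)
    rows[[i]] <- data.frame(
      penetration = penetration, band = bd, condition = cn,
      mean_accuracy = dec$mean,
      shuffle_mean = if (is.null(shuf)) NA_real_ else shuf$mean,
      n_tot = nTot, n_sites = nSites(session), seed = seed,
      sub1_accuracy = dec$perSub[1L],
      sub2_accuracy = if (length(dec$perSub) > 1L) dec$perSub[2L]
                      else NA_real_,
      stringsAsFactors = FALSE)
    scores[[paste(bd, cn, sep = ".")]] <- dec$perRep
  }
  methods::new("DecodingResult",
    table = do.call(rbind, rows), repScores = scores,
    params = list(nRep = nRep, nShuffle = nShuffle, cost = cost,
                  window = params$window, seed = seed,
                  siteFraction = siteFraction))
}
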