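#' @include AllClasses.R
NULL

#' Preprocessing parameters
#'
#' Bundle of the cleaning and windowing parameters applied to raw LFP
#' before spectral estimation: a 48-52 Hz fourth-order Butterworth
#' band-stop (line-noise notch) applied zero-phase, exclusion of trials
#' whose signal reaches below 1\% or above 99\% of the declared input
#' range, and the early analysis window of 60-310 ms post stimulus onset.
#'
#' @param notchBand Hz pair, stop band of the notch.
#' @param notchOrder order of the band-stop filter (must be even; the
#'   Butterworth prototype order is \code{notchOrder / 2}).
#' @param clipLow,clipHigh clipping thresholds as fractions of the total
#'   input range.
#' @param window analysis window in ms relative to stimulus onset,
#'   half-open \code{[start, end)}.
#' @return a validated list of class \code{PreprocessParams}.
#' @examples
#' preprocessParams()
#' @export
preprocessParams <- function(notchBand = c(48, 52), notchOrder = 4L,
                             clipLow = 0.01, clipHigh = 0.99,
                             window = c(60, 310)) {
  stopifnot(length(notchBand) == 2L, notchBand[1L] < notchBand[2L],
            notchOrder >= 2L, notchOrder %% 2L == 0L,
            clipLow >= 0, clipLow < clipHigh, clipHigh <= 1,
            length(window) == 2L, window[1L] < window[2L])
  structure(list(notchBand = notchBand, notchOrder = as.integer(notchOrder),
                 clipLow = clipLow, clipHigh = clipHigh, window = window),
            class = "PreprocessParams")
}

#' Zero-phase Butterworth notch filter
#'
#' Applies a Butterworth band-stop filter forward and backward
#' (zero-phase, so the analysis-window alignment is not shifted) to remove
#' the 50 Hz line component. Accepts a vector (one trace) or a matrix with
#' time along the last dimension.
#'
#' @param x numeric vector or matrix (rows = channels, columns = time).
#' @param fs sampling rate, Hz.
#' @param params a \code{\link{preprocessParams}} object.
#' @return filtered data, same shape as the input.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' y <- notchFilter(sin(2 * pi * 50 * t), fs = 1000)
#' mean(y^2) / mean(sin(2 * pi * 50 * t)^2)  # residual power
#' @export
notchFilter <- function(x, fs, params = preprocessParams()) {
  band <- params$notchBand
  if (band[2L] >= fs / 2)
    stop("notch band must lie below the Nyquist frequency")
  bf <- signal::butter(params$notchOrder / 2L, band / (fs / 2),
                       type = "stop")
  warmup <- 3L * (max(length(bf$b), length(bf$a)) - 1L)
  apply1 <- function(v) {
    if (any(!is.finite(v))) stop("trace contains non-finite samples")
    if (length(v) <= warmup)
      stop("trace shorter than the filter warm-up period")
    signal::filtfilt(bf, v)
  }
  if (is.matrix(x)) t(apply(x, 1L, apply1)) else apply1(x)
}

#' Apply the notch filter to every trial and site of a session
#'
#' @param session a \linkS4class{SessionRecording}.
#' @param params a \code{\link{preprocessParams}} object.
#' @return the session with filtered LFP.
#' @export
notchFilterSession <- function(session, params = preprocessParams()) {
  lfp <- session@lfp
  d <- dim(lfp)
  flat <- matrix(aperm(lfp, c(3L, 1L, 2L)), nrow = d[3L])  # time x (trial*site)
  bf <- signal::butter(params$notchOrder / 2L,
                       params$notchBand / (session@samplingRate / 2),
                       type = "stop")
  for (j in seq_len(ncol(flat))) flat[, j] <- signal::filtfilt(bf, flat[, j])
  session@lfp <- aperm(array(flat, dim = c(d[3L], d[1L], d[2L])),
                       c(2L, 3L, 1L))
  session
}

#' Reject trials that reach the edges of the input range
#'
#' A trial is rejected if and only if any sample on any analysed site
#' falls at or below \code{clipLow}, or at or above \code{clipHigh}, of the
#' total declared input range (amplifier clipping). Aborted trials are
#' dropped as well since they are never analysed. The input range must be
#' declared in the session metadata; it is never inferred from the data.
#'
#' @param session a \linkS4class{SessionRecording}.
#' @param params a \code{\link{preprocessParams}} object.
#' @return list with elements \code{session} (retained trials only),
#'   \code{rejected} (data frame \code{trial_id}, \code{site},
#'   \code{reason}) giving the rejection log.
#' @export
rejectClippedTrials <- function(session, params = preprocessParams()) {
  rng <- session@inputRange
  if (length(rng) != 2L || any(!is.finite(rng)) || diff(rng) <= 0)
    stop("input range not declared in session metadata; ",
         "clipping rejection requires the declared range and never infers it")
  lo <- rng[1L] + params$clipLow * diff(rng)
  hi <- rng[1L] + params$clipHigh * diff(rng)
  n <- nTrials(session)
  log <- vector("list", n)
  drop <- logical(n)
  for (i in seq_len(n)) {
    if (session@trials$aborted[i]) {
      drop[i] <- TRUE
      log[[i]] <- data.frame(trial_id = session@trials$trial_id[i],
                             site = NA_integer_, reason = "aborted")
      next
    }
    m <- session@lfp[i, , , drop = FALSE]
    bad <- which(apply(m[1L, , , drop = FALSE] <= lo |
                       m[1L, , , drop = FALSE] >= hi, 2L, any))
    if (length(bad)) {
      drop[i] <- TRUE
      log[[i]] <- data.frame(trial_id = session@trials$trial_id[i],
                             site = bad[1L], reason = "clipped")
    }
  }
  keep <- !drop
  kept <- session
  kept@lfp <- session@lfp[keep, , , drop = FALSE]
  if (!is.null(session@spikes))
    kept@spikes <- session@spikes[keep, , , drop = FALSE]
  kept@trials <- session@trials[keep, , drop = FALSE]
  rownames(kept@trials) <- NULL
  list(session = kept,
       rejected = if (any(drop)) do.call(rbind, log[drop])
                  else data.frame(trial_id = integer(0), site = integer(0),
                                  reason = character(0)))
}

#' Extract the analysis window of one epoch
#'
#' Returns the samples in \code{[onset + window[1], onset + window[2])}
#' (half-open, so the default 60-310 ms window holds exactly 250 samples
#' at 1 kHz).
#'
#' @param trace numeric vector (one site) or matrix (sites x time).
#' @param onsetMs stimulus onset in ms relative to trace start.
#' @param windowMs ms pair relative to onset.
#' @param fs sampling rate, Hz.
#' @return windowed trace, same row structure as the input.
#' @examples
#' x <- seq_len(2500)
#' length(extractEpoch(x, onsetMs = 500, fs = 1000))  # 250
#' @export
extractEpoch <- function(trace, onsetMs, windowMs = c(60, 310), fs = 1000) {
  idx <- epochIndices(onsetMs, windowMs, fs,
                      nSamples = if (is.matrix(trace)) ncol(trace)
                                 else length(trace))
  if (is.matrix(trace)) trace[, idx, drop = FALSE] else trace[idx]
}

## Half-open sample indices of [onset+w1, onset+w2) ms, 1-based.
epochIndices <- function(onsetMs, windowMs, fs, nSamples) {
  if (windowMs[2L] <= windowMs[1L])
    stop("analysis window must have positive length")
  a <- round((onsetMs + windowMs[1L]) * fs / 1000) + 1L
  b <- round((onsetMs + windowMs[2L]) * fs / 1000)
  if (a < 1L || b > nSamples)
    stop("analysis window exceeds the recorded trace")
  seq.int(a, b)
}
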