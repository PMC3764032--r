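#' @include AllClasses.R bands.R preprocess.R
NULL

## sigma_t in seconds for centre frequency f0 under constant f0/sigma_f.
sigmaT <- function(f0, ratio = 7) ratio / (2 * pi * f0)

#' Complex Morlet wavelet
#'
#' Samples a complex Morlet wavelet with centre frequency \code{f0} and
#' constant centre-frequency to spectral-bandwidth ratio
#' \code{f0 / sigma_f = ratio}. The temporal envelope is Gaussian with
#' \code{sigma_t = 1 / (2 pi sigma_f)}; support is truncated at
#' \code{+/- 4 sigma_t} (Gaussian tail < 1e-4) and the wavelet carries
#' unit L2 energy, so power across centre frequencies compares signal
#' energy density.
#'
#' @param f0 centre frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param ratio \code{f0 / sigma_f} (dimensionless).
#' @return complex vector of odd length \code{2L + 1}, centred at
#'   \code{L + 1}.
#' @export
morletWavelet <- function(f0, fs, ratio = 7) {
  st <- sigmaT(f0, ratio)
  L <- ceiling(4 * st * fs)
  t <- (-L:L) / fs
  w <- exp(-t^2 / (2 * st^2)) * exp(2i * pi * f0 * t)
  w / sqrt(sum(Mod(w)^2) / fs)            # unit energy
}

## Spectrum of the centred wavelet zero-padded to length N (cached).
.waveletCache <- new.env(parent = emptyenv())

waveletSpectrum <- function(f0, fs, ratio, N) {
  key <- sprintf("%g-%g-%g-%d", f0, fs, ratio, N)
  hit <- .waveletCache[[key]]
  if (!is.null(hit)) return(hit)
  w <- morletWavelet(f0, fs, ratio)
  L <- (length(w) - 1L) %/% 2L
  if (N < length(w)) stop("FFT length shorter than wavelet support")
  kpad <- complex(N)
  kpad[seq_len(L + 1L)] <- w[(L + 1L):(2L * L + 1L)]
  kpad[(N - L + 1L):N] <- w[seq_len(L)]
  out <- stats::fft(kpad)
  assign(key, out, envir = .waveletCache)
  out
}

#' Time-frequency power via Morlet wavelet convolution
#'
#' Convolves a single trace with complex Morlet wavelets on a grid of
#' centre frequencies and returns squared magnitude (power) as a
#' frequency x time matrix. The trace is zero-extended, so edge samples
#' are attenuated; samples within \code{3 sigma_t} of either trace end are
#' edge-flagged per frequency (attribute \code{edgeMargin}, in samples).
#' Frequencies whose \code{6 sigma_t} support exceeds the trace length are
#' marked invalid (attribute \code{invalid}) and returned as \code{NA}
#' rows rather than silently estimated.
#'
#' @param x numeric trace.
#' @param freqs centre-frequency grid, Hz (default 1-170 in 1 Hz steps).
#' @param fs sampling rate, Hz.
#' @param ratio \code{f0 / sigma_f}.
#' @return numeric matrix \code{length(freqs)} x \code{length(x)} with
#'   attributes \code{freqs}, \code{edgeMargin} and \code{invalid}.
#' @examples
#' x <- cos(2 * pi * 40 * seq(0, 2, by = 1e-3))
#' p <- morletPower(x, freqs = 30:50, fs = 1000)
#' which.max(rowMeans(p[, 500:1500])) + 29  # peaks at 40 Hz
#' @export
morletPower <- function(x, freqs = 1:170, fs = 1000, ratio = 7) {
  if (any(!is.finite(x))) stop("trace contains non-finite samples")
  n <- length(x)
  st <- sigmaT(freqs, ratio)
  invalid <- (6 * st * fs) > n
  Lmax <- ceiling(4 * max(st[!invalid], 0) * fs)
  N <- stats::nextn(n + 2L * Lmax + 1L, c(2L, 3L, 5L))
  X <- stats::fft(c(x, numeric(N - n)))
  out <- matrix(NA_real_, length(freqs), n)
  for (i in seq_along(freqs)) {
    if (invalid[i]) next
    W <- waveletSpectrum(freqs[i], fs, ratio, N)
    y <- stats::fft(X * W, inverse = TRUE) / N
    out[i, ] <- Mod(y[seq_len(n)])^2
  }
  structure(out, freqs = freqs,
            edgeMargin = pmin(ceiling(3 * st * fs), n),
            invalid = invalid)
}

#' Average time-frequency power within bands and an analysis window
#'
#' Arithmetic mean of \code{\link{morletPower}} output over the integer
#' grid frequencies of each band and the time samples of the analysis
#' window. Requests touching edge-flagged or invalid samples are
#' rejected rather than silently averaged.
#'
#' @param power output of \code{\link{morletPower}}.
#' @param bands band definition table.
#' @param windowIdx integer sample indices of the analysis window.
#' @return named numeric vector, one mean power per band.
#' @export
bandAverage <- function(power, bands = defaultBands(), windowIdx) {
  validateBands(bands)
  freqs <- attr(power, "freqs")
  margin <- attr(power, "edgeMargin")
  invalid <- attr(power, "invalid")
  n <- ncol(power)
  out <- stats::setNames(numeric(nrow(bands)), bands$name)
  for (b in seq_len(nrow(bands))) {
    grid <- bandGrid(bands$lo[b], bands$hi[b])
    rows <- match(grid, freqs)
    if (any(is.na(rows)))
      stop(sprintf("band %s requests frequencies outside the computed grid",
                   bands$name[b]))
    if (any(invalid[rows]))
      stop(sprintf("band %s includes frequencies invalid for this trace length",
                   bands$name[b]))
    m <- max(margin[rows])
    if (min(windowIdx) <= m || max(windowIdx) > n - m)
      stop(sprintf("analysis window overlaps edge-flagged samples for band %s",
                   bands$name[b]))
    out[b] <- mean(power[rows, windowIdx, drop = FALSE])
  }
  out
}

#' Band power table of a session
#'
#' Computes the per-trial, per-site, per-band scalar power of both epochs
#' (adapter and test) of every trial: Morlet power on the integer
#' frequency grid of each band, averaged over the band frequencies and
#' the analysis window. The wavelet convolution runs on the full-length
#' trace segment that covers the analysis window plus the complete
#' wavelet support, so the result is identical to convolving the whole
#' trial and windowing afterwards, with no convolution edge effects
#' inside the window.
#'
#' @param session a \linkS4class{SessionRecording} (preprocessed: notch
#'   filtered, clipped and aborted trials removed).
#' @param bands band definition table.
#' @param params a \code{\link{preprocessParams}} object (analysis window).
#' @param ratio wavelet \code{f0 / sigma_f}.
#' @return a \linkS4class{BandPowerTable}.
#' @export
bandPower <- function(session, bands = defaultBands(),
                      params = preprocessParams(), ratio = 7) {
  validateBands(bands)
  fs <- session@samplingRate
  d <- dim(session@lfp)
  nTr <- d[1L]; nS <- d[2L]; nT <- d[3L]
  epochs <- c("adapter", "test")
  pow <- array(NA_real_, dim = c(nTr, nS, nrow(bands), 2L),
               dimnames = list(NULL, NULL, bands$name, epochs))
  for (e in seq_along(epochs)) {
    widx <- epochIndices(session@onsets[[epochs[e]]], params$window, fs, nT)
    for (b in seq_len(nrow(bands))) {
      grid <- bandGrid(bands$lo[b], bands$hi[b])
      Lmax <- ceiling(4 * sigmaT(min(grid), ratio) * fs)
      segA <- min(widx) - Lmax
      segB <- max(widx) + Lmax
      if (segA < 1L || segB > nT)
        stop(sprintf(
          "band %s: analysis window closer than the wavelet support to a trace end",
          bands$name[b]))
      seg <- seq.int(segA, segB)
      rel <- widx - segA + 1L
      N <- stats::nextn(length(seg) + 2L * Lmax + 1L, c(2L, 3L, 5L))
      for (s in seq_len(nS)) {
        X <- matrix(0, N, nTr)
        X[seq_along(seg), ] <- t(session@lfp[, s, seg])
        Fx <- stats::mvfft(X + 0i)
        acc <- matrix(0, length(rel), nTr)
        for (f in grid) {
          W <- waveletSpectrum(f, fs, ratio, N)
          Y <- stats::mvfft(Fx * W, inverse = TRUE) / N
          acc <- acc + Mod(Y[rel, , drop = FALSE])^2
        }
        pow[, s, b, e] <- colMeans(acc) / length(grid)
      }
    }
  }
  methods::new("BandPowerTable", power = pow, bands = bands,
               trials = session@trials, window = params$window)
}

#' Tidy serialisation of a band power table
#'
#' @param x a \linkS4class{BandPowerTable}.
#' @return data frame with columns \code{trial_id}, \code{site},
#'   \code{epoch}, \code{band}, \code{power}.
#' @export
bandPowerToDataFrame <- function(x) {
  d <- dim(x@power)
  expand <- expand.grid(trial = seq_len(d[1L]), site = seq_len(d[2L]),
                        band = x@bands$name,
                        epoch = c("adapter", "test"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(trial_id = x@trials$trial_id[expand$trial],
             site = expand$site, epoch = expand$epoch, band = expand$band,
             power = as.vector(x@power), stringsAsFactors = FALSE)
}
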