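#' Canonical LFP frequency bands
#'
#' The five band definitions used throughout the package, inclusive on the
#' 1 Hz integer wavelet grid: alpha 8-12, beta 13-30, low gamma 31-60,
#' middle gamma 61-100 and high gamma 101-170 Hz. Under the inclusive
#' reading the bands partition 8-170 Hz without overlap.
#'
#' @return data frame with columns \code{name}, \code{lo}, \code{hi}.
#' @examples
#' defaultBands()
#' @export
defaultBands <- function() {
  data.frame(
    name = c("alpha", "beta", "low_gamma", "middle_gamma", "high_gamma"),
    lo = c(8, 13, 31, 61, 101),
    hi = c(12, 30, 60, 100, 170),
    stringsAsFactors = FALSE
  )
}

#' Validate a band definition table
#'
#' Checks that bands are non-empty on the integer frequency grid, ordered
#' and mutually disjoint. Called by every function that accepts a custom
#' band table.
#'
#' @param bands data frame with columns \code{name}, \code{lo}, \code{hi}.
#' @return the validated table, invisibly.
#' @export
validateBands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("name", "lo", "hi") %in% names(bands)))
  if (any(bands$hi < bands$lo))
    stop("band with zero grid frequencies: hi < lo")
  if (any(floor(bands$hi) < ceiling(bands$lo)))
    stop("band contains no integer grid frequency")
  o <- order(bands$lo)
  if (nrow(bands) > 1L) {
    so <- bands[o, ]
    if (any(so$lo[-1L] <= so$hi[-nrow(so)]))
      stop("band ranges must be disjoint")
  }
  invisible(bands)
}

## integer grid frequencies belonging to one band (inclusive edges)
bandGrid <- function(lo, hi) seq.int(ceiling(lo), floor(hi))
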