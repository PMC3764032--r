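#' @include AllClasses.R
NULL

#' Write a session to a portable directory container
#'
#' One directory per penetration holding \code{metadata.json} (sampling
#' rate, site count and spacing, declared input range, onsets, array
#' dimensions), \code{trials.csv}, and the LFP tensor and spike counts as
#' flat little-endian float64 arrays (\code{lfp.f64}, \code{spikes.f64})
#' stored row-major in the dimension order recorded in the metadata
#' (trial x site x time; the last index varies fastest).
#'
#' @param session a \linkS4class{SessionRecording}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(session@lfp)
  meta <- list(
    format = "adaptdecode-session-v1",
    sampling_rate_hz = session@samplingRate,
    site_spacing_um = session@siteSpacing,
    input_range = session@inputRange,
    onsets_ms = as.list(session@onsets),
    lfp_dims = d, lfp_order = c("trial", "site", "time"),
    spikes_dims = if (is.null(session@spikes)) NULL else dim(session@spikes),
    storage = "float64 little-endian, row-major (last index fastest)")
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(session@trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "lfp.f64"), "wb")
  writeBin(as.vector(aperm(session@lfp, c(3L, 2L, 1L))), con,
           size = 8L, endian = "little")
  close(con)
  if (!is.null(session@spikes)) {
    con <- file(file.path(dir, "spikes.f64"), "wb")
    writeBin(as.vector(aperm(session@spikes * 1.0, c(3L, 2L, 1L))), con,
             size = 8L, endian = "little")
    close(con)
  }
  invisible(dir)
}

#' Read a session written by \code{\link{writeSession}}
#'
#' @param dir session directory.
#' @return a \linkS4class{SessionRecording}.
#' @export
readSession <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "adaptdecode-session-v1"))
    stop("unrecognised session container format")
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  d <- as.integer(meta$lfp_dims)
  con <- file(file.path(dir, "lfp.f64"), "rb")
  v <- readBin(con, "double", n = prod(d), size = 8L, endian = "little")
  close(con)
  lfp <- aperm(array(v, dim = rev(d)), c(3L, 2L, 1L))
  spikes <- NULL
  spikesPath <- file.path(dir, "spikes.f64")
  if (file.exists(spikesPath)) {
    ds <- as.integer(meta$spikes_dims)
    con <- file(spikesPath, "rb")
    sv <- readBin(con, "double", n = prod(ds), size = 8L, endian = "little")
    close(con)
    spikes <- aperm(array(sv, dim = rev(ds)), c(3L, 2L, 1L))
    dimnames(spikes) <- list(NULL, NULL, c("adapter", "test"))
  }
  methods::new("SessionRecording",
    lfp = lfp, spikes = spikes, trials = trials,
    samplingRate = meta$sampling_rate_hz,
    siteSpacing = meta$site_spacing_um,
    inputRange = as.numeric(meta$input_range),
    onsets = c(adapter = meta$onsets_ms$adapter,
               test = meta$onsets_ms$test),
    groundTruth = list())
}
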