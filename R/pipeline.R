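#' @include AllClasses.R decode.R stats.R
NULL

#' Run the full adaptation-decoding experiment on synthetic penetrations
#'
#' End-to-end orchestration: simulate \code{nPenetrations} sessions from a
#' template configuration (per-penetration seeds derived from the master
#' seed), preprocess each (notch filter, clipped/aborted-trial
#' rejection), compute Morlet band power, decode every band (and
#' optionally spike counts) for the four stimulus conditions with one
#' shared \code{N_tot} per penetration, then aggregate across
#' penetrations: a condition x band mean/SEM summary table and
#' repeated-measures statistics (two-way band x condition ANOVA and
#' per-band one-way ANOVAs with Bonferroni post-hoc comparisons).
#'
#' @param config template \linkS4class{SimulationConfig}.
#' @param nPenetrations number of simulated penetrations.
#' @param bands band definition table.
#' @param params a \code{\link{preprocessParams}} object.
#' @param nRep classifier repetitions per condition.
#' @param nShuffle label permutations for the shuffle control (0 = skip).
#' @param seed master seed of the run.
#' @param mua also decode spike-count features.
#' @param outDir if non-\code{NULL}, write \code{results.csv},
#'   \code{summary.csv}, \code{stats.txt} and \code{manifest.json} there.
#' @return list with \code{results} (tidy per-penetration table),
#'   \code{summary} (condition x band mean and SEM),
#'   \code{anova} (list of effect tables), \code{posthoc} (per-band
#'   pairwise comparisons) and \code{manifest}.
#' @export
runExperiment <- function(config, nPenetrations = 2, bands = defaultBands(),
                          params = preprocessParams(), nRep = 100,
                          nShuffle = 0, seed = 1, mua = TRUE,
                          outDir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  penSeeds <- deriveSeeds(seed, 2L * nPenetrations)
  results <- vector("list", nPenetrations)
  for (i in seq_len(nPenetrations)) {
    cfg <- config
    cfg@seed <- penSeeds[i]
    ses <- simulateSession(cfg, bands)
    res <- decodeSession(ses, bands, params, nRep = nRep,
                         nShuffle = nShuffle,
                         seed = penSeeds[nPenetrations + i],
                         penetration = sprintf("pen%02d", i), mua = mua)
    results[[i]] <- resultTable(res)
  }
  results <- do.call(rbind, results)
  summaryTab <- summarizeResults(results)
  lfpRows <- results[results$band != "MUA", ]
  anova <- list(
    band_by_condition = rmAnova(lfpRows, "mean_accuracy",
                                c("band", "condition"), "penetration"))
  posthoc <- list()
  for (b in unique(lfpRows$band)) {
    sub <- lfpRows[lfpRows$band == b, ]
    anova[[paste0("condition_", b)]] <-
      rmAnova(sub, "mean_accuracy", "condition", "penetration")
    posthoc[[b]] <- bonferroniPosthoc(sub, "mean_accuracy", "condition",
                                      "penetration")
  }
  manifest <- list(
    package = "adaptdecode",
    version = as.character(utils::packageVersion("adaptdecode")),
    seed = seed, n_penetrations = nPenetrations,
    n_classifiers = nRep, n_shuffle = nShuffle,
    bands = bands$name, window_ms = params$window,
    config = list(n_sites = config@nSites,
                  n_trials_per_sequence = config@nTrialsPerSequence,
                  repetition_gain = as.list(config@repetitionGain),
                  cross_adaptation_gain = as.list(config@crossAdaptationGain)),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(outDir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(summaryTab, file.path(outDir, "summary.csv"),
                     row.names = FALSE)
    writeStatsReport(anova, posthoc, file.path(outDir, "stats.txt"))
    manifest$file_md5 <- as.list(tools::md5sum(
      file.path(outDir, c("results.csv", "summary.csv", "stats.txt"))))
    names(manifest$file_md5) <- c("results.csv", "summary.csv", "stats.txt")
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(results = results, summary = summaryTab, anova = anova,
       posthoc = posthoc, manifest = manifest)
}

#' Condition x band summary across penetrations
#'
#' Mean classification accuracy and its standard error over penetrations
#' for every band x condition cell.
#'
#' @param results tidy results table from \code{\link{runExperiment}} or
#'   stacked \code{\link{decodeSession}} tables.
#' @return data frame with \code{band}, \code{condition}, \code{mean},
#'   \code{sem}, \code{n}. With a single penetration the SEM is
#'   \code{NA} and a warning is raised.
#' @export
summarizeResults <- function(results) {
  sp <- split(results, list(results$band, results$condition), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    n <- nrow(d)
    data.frame(band = d$band[1L], condition = d$condition[1L],
               mean = mean(d$mean_accuracy),
               sem = if (n > 1L) stats::sd(d$mean_accuracy) / sqrt(n)
                     else NA_real_,
               n = n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (any(out$n < 2L))
    warning("SEM undefined with a single penetration")
  out[order(out$band, out$condition), ]
}

## Human-readable statistics report.
writeStatsReport <- function(anova, posthoc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(anova)) {
    writeLines(sprintf("== %s ==", nm), con)
    tab <- anova[[nm]]
    for (i in seq_len(nrow(tab)))
      writeLines(sprintf("  %-20s F(%d,%d) = %.4f, p = %.3g",
                         tab$effect[i], tab$df[i], tab$df_error[i],
                         tab$F[i], tab$p[i]), con)
  }
  for (b in names(posthoc)) {
    writeLines(sprintf("== post-hoc (%s), Bonferroni ==", b), con)
    ph <- posthoc[[b]]
    for (i in seq_len(nrow(ph)))
      writeLines(sprintf("  %s vs %s: diff = %.2f, t(%d) = %.3f, p_adj = %.3g",
                         ph$level1[i], ph$level2[i], ph$diff[i], ph$df[i],
                         ph$t[i], ph$p_adjusted[i]), con)
  }
}
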