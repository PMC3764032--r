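#' @include AllClasses.R
NULL

#' Repeated-measures analysis of variance
#'
#' One- or two-way repeated-measures ANOVA with the penetration (subject)
#' as the blocking factor, for balanced within-subject designs: every
#' subject contributes exactly one observation per factor-level cell.
#' Sums of squares are partitioned by \code{stats::aov} with the
#' appropriate within-subject error strata; no sphericity correction is
#' applied by default (a Greenhouse-Geisser option exists for one-way
#' designs). Degenerate effects (zero effect and zero error variance,
#' e.g. all cells identical) are reported as \code{F = 0, p = 1}.
#'
#' @param data long-format data frame.
#' @param dv name of the dependent-variable column (accuracy, \%).
#' @param within character vector of one or two within-subject factor
#'   column names.
#' @param subject name of the subject (penetration) column.
#' @param gg apply the Greenhouse-Geisser sphericity correction
#'   (one-way designs only).
#' @return data frame with one row per effect: \code{effect}, \code{df},
#'   \code{df_error}, \code{ss}, \code{ss_error}, \code{F}, \code{p}
#'   (and \code{gg_epsilon} when corrected). The pooled within-subject
#'   error terms are attached as attribute \code{errorTerms}.
#' @examples
#' d <- expand.grid(pen = factor(1:6), cond = factor(c("a", "b", "c")))
#' d$acc <- 60 + as.integer(d$cond) + rnorm(nrow(d))
#' rmAnova(d, "acc", "cond", "pen")
#' @export
rmAnova <- function(data, dv, within, subject, gg = FALSE) {
  stopifnot(length(within) %in% 1:2, all(c(dv, within, subject) %in%
                                           names(data)))
  for (v in c(within, subject)) data[[v]] <- factor(data[[v]])
  cellCount <- table(data[c(subject, within)])
  if (any(cellCount != 1L))
    stop("unbalanced design: each subject needs exactly one observation ",
         "per factor-level cell")
  errSpec <- paste(within, collapse = "*")
  form <- stats::as.formula(sprintf("%s ~ %s + Error(%s/(%s))",
                                    dv, errSpec, subject, errSpec))
  fit <- stats::aov(form, data = data)
  sm <- summary(fit)
  rows <- list(); errTerms <- list()
  for (stratum in sm) {
    tab <- stratum[[1L]]
    eff <- trimws(rownames(tab))
    resid <- eff == "Residuals"
    if (!any(!resid) || !any(resid)) next
    dfE <- tab[resid, "Df"]; ssE <- tab[resid, "Sum Sq"]
    scale <- mean(data[[dv]]^2) + .Machine$double.xmin
    for (i in which(!resid)) {
      Fv <- tab[i, "F value"]; pv <- tab[i, "Pr(>F)"]
      ## degenerate cell structure (e.g. all cells identical): both the
      ## effect and its error variance vanish; report no effect
      if (!is.finite(Fv) || tab[i, "Sum Sq"] <= 1e-12 * scale) {
        Fv <- 0; pv <- 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        effect = eff[i], df = tab[i, "Df"], df_error = dfE,
        ss = tab[i, "Sum Sq"], ss_error = ssE, F = Fv, p = pv,
        stringsAsFactors = FALSE)
      errTerms[[eff[i]]] <- list(ms_error = ssE / dfE, df_error = dfE)
    }
  }
  out <- do.call(rbind, rows)
  if (gg) {
    if (length(within) != 1L)
      stop("Greenhouse-Geisser correction implemented for one-way designs")
    eps <- ggEpsilon(data, dv, within, subject)
    out$gg_epsilon <- eps
    out$p <- stats::pf(out$F, out$df * eps, out$df_error * eps,
                       lower.tail = FALSE)
    out$p[out$F == 0] <- 1
  }
  attr(out, "errorTerms") <- errTerms
  out
}

## Greenhouse-Geisser epsilon from the subject x level matrix.
ggEpsilon <- function(data, dv, within, subject) {
  m <- tapply(data[[dv]], list(data[[subject]], data[[within]]), mean)
  S <- stats::cov(m)
  k <- ncol(S)
  dbar <- mean(diag(S)); gbar <- mean(S)
  rowbar <- rowMeans(S)
  num <- (k * (dbar - gbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowbar^2) + k^2 * gbar^2)
  max(1 / (k - 1), min(1, num / den))
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' Pairwise comparisons between levels of a within-subject factor after a
#' repeated-measures ANOVA, using the pooled within-subject error term of
#' that ANOVA: \code{t = (m_i - m_j) / sqrt(2 MSE / n)} on the ANOVA
#' error degrees of freedom. Raw p-values are multiplied by the number of
#' comparisons and capped at 1.
#'
#' @param data,dv,within,subject as in \code{\link{rmAnova}} (one factor).
#' @param pairs optional list of level pairs (character vectors of length
#'   2); defaults to all pairs.
#' @return data frame with \code{level1}, \code{level2}, \code{diff},
#'   \code{t}, \code{df}, \code{p_raw}, \code{p_adjusted}.
#' @export
bonferroniPosthoc <- function(data, dv, within, subject, pairs = NULL) {
  stopifnot(length(within) == 1L)
  an <- rmAnova(data, dv, within, subject)
  err <- attr(an, "errorTerms")[[within]]
  lev <- levels(factor(data[[within]]))
  if (is.null(pairs))
    pairs <- utils::combn(lev, 2L, simplify = FALSE)
  for (p in pairs)
    if (!all(p %in% lev))
      stop("post-hoc pair references an absent factor level")
  n <- nlevels(factor(data[[subject]]))
  means <- tapply(data[[dv]], factor(data[[within]]), mean)
  m <- length(pairs)
  out <- lapply(pairs, function(p) {
    dd <- means[[p[1L]]] - means[[p[2L]]]
    se <- sqrt(2 * err$ms_error / n)
    tv <- if (se == 0) 0 else dd / se
    praw <- if (se == 0 && dd == 0) 1 else
      2 * stats::pt(abs(tv), err$df_error, lower.tail = FALSE)
    data.frame(level1 = p[1L], level2 = p[2L], diff = dd, t = tv,
               df = err$df_error, p_raw = praw,
               p_adjusted = min(1, praw * m), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided (by default) Wilcoxon signed-rank test on paired
#' observations. Zero differences are dropped (Wilcoxon's original
#' treatment); the p-value is exact for up to 25 non-zero differences
#' without ties, and uses the normal approximation with continuity
#' correction otherwise. When every difference is zero the test is
#' undefined and \code{p = 1} is reported with a flag.
#'
#' @param x,y paired numeric vectors.
#' @param alternative \code{"two.sided"}, \code{"less"} or
#'   \code{"greater"}.
#' @return list with \code{statistic} (V), \code{p.value}, \code{n}
#'   (non-zero pairs), \code{exact} and \code{allZero}.
#' @examples
#' wilcoxonMatchedPairs(c(1, 2, 3, 4, 5, 6), c(0, 1, 2, 3, 4, 5))
#' @export
wilcoxonMatchedPairs <- function(x, y, alternative = "two.sided") {
  if (length(x) != length(y))
    stop("paired vectors must have equal length")
  d <- x - y
  nz <- d[d != 0]
  if (!length(nz))
    return(list(statistic = NA_real_, p.value = 1, n = 0L,
                exact = FALSE, allZero = TRUE))
  n <- length(nz)
  exact <- n <= 25L && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value, n = n,
       exact = exact, allZero = FALSE)
}
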