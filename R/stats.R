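# Group-level statistics: fold changes, paired t-tests, one-way ANOVA with
# Bonferroni-corrected pairwise comparisons, and a structured group report.

#' Fold change and percent change between two means
#'
#' `fold = b / a`, `pct_change = 100 * (b - a) / a`; the two are mutually
#' consistent (`fold = 1 + pct_change / 100`).  Conventionally printed to 2
#' and 1 decimals respectively (see the print method); raw values returned.
#'
#' @param a reference mean, `> 0`.
#' @param b comparison mean.
#' @return Object of class `foldChange`: list `fold`, `pct_change`.
#' @export
foldChange <- function(a, b) {
  if (!is.finite(a) || a <= 0) stop("reference mean must be positive")
  structure(list(fold = b / a, pct_change = 100 * (b - a) / a),
            class = "foldChange")
}

#' @export
print.foldChange <- function(x, ...) {
  cat(sprintf("%.2f-fold (%+.1f%%)\n", x$fold, x$pct_change))
  invisible(x)
}

#' Two-sided paired Student t-test
#'
#' @param x,y paired numeric vectors of equal length `>= 3`.
#' @return List `t`, `p`, `df`.  When the paired differences have zero
#'   variance: identical vectors give `t = 0, p = 1`; constant nonzero
#'   differences raise a "zero-variance differences" error.
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = length(d) - 1L))
    stop("zero-variance differences")
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' One-way ANOVA with Bonferroni-corrected pairwise t-tests
#'
#' Standard one-way F test on `k = 3` groups, plus equal-variance pairwise
#' t-tests flagged significant at the Bonferroni level `alpha / 3`
#' (default 0.05 / 3, about 0.017).
#'
#' @param groups list of 3 numeric vectors, each of length `>= 2`.
#' @param alpha familywise level before correction (default 0.05).
#' @return List `F`, `p`, `df` (c(between, within)), `pairwise`
#'   (data frame: pair, t, p, significant), `alpha_corrected`.
#' @export
onewayAnovaBonferroni <- function(groups, alpha = 0.05) {
  if (length(groups) != 3L) stop("need exactly 3 groups")
  if (any(vapply(groups, length, 0L) < 2L)) {
    stop("every group needs at least 2 values")
  }
  vals <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  fit <- lm(vals ~ g)
  an <- anova(fit)
  Fv <- an$`F value`[1L]
  pv <- an$`Pr(>F)`[1L]
  if (!is.finite(Fv)) { Fv <- 0; pv <- 1 }   # all values identical
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("G", seq_along(groups))
  pairs <- combn(3L, 2L)
  alpha_c <- alpha / ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    tt <- t.test(groups[[i]], groups[[j]], var.equal = TRUE)
    data.frame(pair = paste(labs[i], labs[j], sep = " vs "),
               t = unname(tt$statistic), p = tt$p.value,
               significant = tt$p.value < alpha_c)
  }))
  list(F = Fv, p = pv, df = unname(an$Df), pairwise = pw,
       alpha_corrected = alpha_c)
}

#' Build a three-group summary report
#'
#' Mean +/- SD of each metric per group, one-way ANOVA with
#' Bonferroni-corrected pairwise flags, and pre-to-post fold changes, in
#' the column layout `metric, BL_mean, BL_sd, pre_mean, pre_sd, post_mean,
#' post_sd, F, p, flags, fold_pre_post, pct_pre_post`.
#'
#' @param group_metrics named list (`BL`, `PRE_RFT`, `POST_RFT`) of data
#'   frames of per-subject metric columns (same columns in each group,
#'   `>= 2` rows).
#' @return Object of class `groupReport`: list with the summary data frame
#'   `table` and the per-metric ANOVA details `anova`.
#' @export
buildGroupReport <- function(group_metrics) {
  need <- c("BL", "PRE_RFT", "POST_RFT")
  if (!all(need %in% names(group_metrics))) {
    stop("missing group(s): ",
         paste(setdiff(need, names(group_metrics)), collapse = ", "))
  }
  gm <- lapply(group_metrics[need], as.data.frame)
  metrics <- Reduce(intersect, lapply(gm, names))
  if (!length(metrics)) stop("no common metric columns")
  details <- list()
  rows <- lapply(metrics, function(m) {
    cols <- lapply(gm, function(df) df[[m]])
    an <- onewayAnovaBonferroni(setNames(cols, need))
    details[[m]] <<- an
    fc <- foldChange(mean(cols$PRE_RFT), mean(cols$POST_RFT))
    flags <- paste(an$pairwise$pair[an$pairwise$significant], collapse = "; ")
    data.frame(metric = m,
               BL_mean = mean(cols$BL), BL_sd = sd(cols$BL),
               pre_mean = mean(cols$PRE_RFT), pre_sd = sd(cols$PRE_RFT),
               post_mean = mean(cols$POST_RFT), post_sd = sd(cols$POST_RFT),
               F = an$F, p = an$p, flags = flags,
               fold_pre_post = fc$fold, pct_pre_post = fc$pct_change)
  })
  structure(list(table = do.call(rbind, rows), anova = details),
            class = "groupReport")
}

#' @export
print.groupReport <- function(x, ...) {
  cat("<groupReport>\n")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Per-subject metric table for a synthetic cohort
#'
#' Convenience bridge from [makeCohort()] output to [buildGroupReport()]:
#' computes SDNN, rMSSD and (when the record allows) the spectral panel for
#' every subject.
#'
#' @param cohort output of [makeCohort()].
#' @param spectral also compute TP/LF/HF/LF-HF/CR (default TRUE).
#' @return Named list of per-group data frames.
#' @export
cohortMetrics <- function(cohort, spectral = TRUE) {
  lapply(cohort, function(grp) {
    do.call(rbind, lapply(grp, function(subj) {
      base <- data.frame(sdnn = sdnn(subj$intervals),
                         rmssd = rmssd(subj$intervals))
      if (spectral) {
        m <- hrvMetrics(subj$intervals)
        base <- cbind(base, data.frame(tp = m$tp, lf_nu = m$lf_nu,
                                       hf_nu = m$hf_nu, lf_hf = m$lf_hf,
                                       cr = m$cr))
      }
      base
    }))
  })
}
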