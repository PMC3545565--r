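# Stress-level and autonomic-balance classification from HRV metrics, and
# the 22-item simplified Stress Response Index (SRI) questionnaire score.

#' Classify stress level from SDNN
#'
#' Bins (ms): `> 50` NON_STRESSED, `[35, 50]` NORMAL, `[20, 35)` HIGH,
#' `[0, 20)` VERY_HIGH.  The boundary values 35 and 50 fall in NORMAL.
#' Higher SDNN never maps to a worse category.
#'
#' @param sdnn SDNN in ms, `>= 0`.
#' @return One of `"NON_STRESSED"`, `"NORMAL"`, `"HIGH"`, `"VERY_HIGH"`.
#' @export
classifySdnn <- function(sdnn) {
  if (!is.finite(sdnn) || sdnn < 0) stop("sdnn must be a non-negative number")
  if (sdnn > 50) "NON_STRESSED"
  else if (sdnn >= 35) "NORMAL"
  else if (sdnn >= 20) "HIGH"
  else "VERY_HIGH"
}

#' Classify autonomic balance from the LF/HF ratio
#'
#' Bins: `> 2.0` HYPER_SYMPATHETIC (acute-stress pattern), `[0.5, 2.0]`
#' BALANCED, `< 0.5` HYPER_PARASYMPATHETIC (chronic-stress pattern).  Both
#' boundaries belong to BALANCED.
#'
#' @param ratio LF/HF ratio, `>= 0` (may be `Inf`).
#' @return One of `"HYPER_SYMPATHETIC"`, `"BALANCED"`,
#'   `"HYPER_PARASYMPATHETIC"`.
#' @export
classifyLfhf <- function(ratio) {
  if (is.na(ratio) || ratio < 0) stop("ratio must be non-negative")
  if (ratio > 2.0) "HYPER_SYMPATHETIC"
  else if (ratio >= 0.5) "BALANCED"
  else "HYPER_PARASYMPATHETIC"
}

#' Score the simplified SRI questionnaire
#'
#' 22 Likert items, each scored 0 ("not at all") to 4 ("absolutely").  The
#' total ranges 0-88; a total strictly greater than 56 is interpreted as a
#' severe stress state.
#'
#' @param items integer vector of exactly 22 values in `{0, 1, 2, 3, 4}`.
#' @param severe_cutoff severity threshold (default 56; severe means
#'   `total > severe_cutoff`).
#' @return List `total` (integer) and `severe` (logical).
#' @export
scoreSri <- function(items, severe_cutoff = 56) {
  if (length(items) != 22L) {
    stop("SRI response must have exactly 22 items, got ", length(items))
  }
  ok <- is.finite(items) & items %in% 0:4
  if (!all(ok)) stop("invalid SRI item at index ", which(!ok)[1L],
                     " (must be an integer 0-4)")
  total <- sum(items)
  list(total = total, severe = total > severe_cutoff)
}

#' Combined stress assessment from HRV metrics
#'
#' SDNN carries the stress level (overall autonomic regulating capacity);
#' the LF/HF ratio carries the sympatho-vagal balance.
#'
#' @param metrics an `hrvMetrics` object, or anything with fields `sdnn`
#'   and `lf_hf`.
#' @return Object of class `stressAssessment`: `sdnn_level`, `balance`,
#'   and the raw `sdnn` and `lf_hf` values.
#' @export
assessStress <- function(metrics) {
  if (is.null(metrics$sdnn) || is.null(metrics$lf_hf)) {
    stop("metrics must provide sdnn and lf_hf")
  }
  structure(list(sdnn_level = classifySdnn(metrics$sdnn),
                 balance = classifyLfhf(metrics$lf_hf),
                 sdnn = metrics$sdnn, lf_hf = metrics$lf_hf),
            class = "stressAssessment")
}

#' @export
print.stressAssessment <- function(x, ...) {
  cat(sprintf("<stressAssessment> stress: %s (SDNN %.1f ms); balance: %s (LF/HF %.2f)\n",
              x$sdnn_level, x$sdnn, x$balance, x$lf_hf))
  invisible(x)
}
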