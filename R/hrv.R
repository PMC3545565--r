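# Time-domain, frequency-domain, coherence and respiratory summary metrics,
# following the Task Force measurement conventions (intervals in ms, powers
# in ms^2, LF 0.04-0.15 Hz, HF 0.15-0.4 Hz).

asIntervals <- function(x) {
  if (inherits(x, "intervalSeries")) x$intervals else as.numeric(x)
}

#' SDNN: standard deviation of all normal-to-normal intervals
#'
#' @param intervals an [intervalSeries()] or numeric vector of intervals in
#'   ms, length >= 2.
#' @return Sample standard deviation (n - 1 denominator), ms.
#' @export
sdnn <- function(intervals) {
  v <- asIntervals(intervals)
  if (length(v) < 2L) stop("need at least 2 intervals")
  sd(v)
}

#' rMSSD: root mean square of successive interval differences
#'
#' @param intervals an [intervalSeries()] or numeric vector in ms,
#'   length >= 3.
#' @return `sqrt(mean(diff(intervals)^2))`, ms.
#' @export
rmssd <- function(intervals) {
  v <- asIntervals(intervals)
  if (length(v) < 3L) stop("need at least 3 intervals")
  sqrt(mean(diff(v)^2))
}

# Welch power spectral density: Hann window, 50% overlap, one-sided density
# normalised so that the integral over frequency matches the signal variance
# for broadband input.
welchPsd <- function(y, fs, seg_len) {
  n <- length(y)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  k <- 0:(seg_len - 1)
  w <- 0.5 - 0.5 * cos(2 * pi * k / (seg_len - 1))
  U <- sum(w^2)
  acc <- numeric(seg_len)
  for (s0 in starts) {
    seg <- y[s0:(s0 + seg_len - 1)]
    seg <- seg - mean(seg)
    acc <- acc + Mod(fft(seg * w))^2 / (fs * U)
  }
  P <- acc / length(starts)
  nhalf <- seg_len %/% 2 + 1L
  Pone <- P[seq_len(nhalf)]
  if (seg_len %% 2 == 0) {
    Pone[2:(nhalf - 1L)] <- 2 * Pone[2:(nhalf - 1L)]
  } else {
    Pone[2:nhalf] <- 2 * Pone[2:nhalf]
  }
  list(freq = (seq_len(nhalf) - 1) * fs / seg_len, power = Pone)
}

#' Power spectral density of an interbeat-interval series
#'
#' The irregularly sampled interval tachogram is interpolated with a cubic
#' spline onto a uniform grid (default 4 Hz), linearly detrended, and a
#' Welch estimate (120 s segments, 50% overlap, Hann window) is computed.
#' The integral of the returned density is checked against the variance of
#' the resampled series (Parseval); a deviation beyond 10% raises a warning
#' and the ratio is stored in the result.
#'
#' @param intervals an [intervalSeries()] (using its `times`) or numeric
#'   vector of intervals in ms.
#' @param beat_times times in seconds of the beat ending each interval;
#'   taken from `intervals$times` when omitted.  The record must span at
#'   least 2 minutes.
#' @param fs_interp resampling rate in Hz (default 4).
#' @param seg_len_s Welch segment length in seconds (default 120).
#' @return Object of class `rrSpectrum`: list with `freq` (Hz), `power`
#'   (ms^2/Hz), `var_resampled` (ms^2) and `parseval_ratio`.
#' @export
rrPsd <- function(intervals, beat_times = NULL, fs_interp = 4,
                  seg_len_s = 120) {
  v <- asIntervals(intervals)
  if (is.null(beat_times) && inherits(intervals, "intervalSeries")) {
    beat_times <- intervals$times
  }
  if (is.null(beat_times)) stop("beat_times required")
  if (length(beat_times) != length(v)) stop("beat_times must parallel intervals")
  span <- diff(range(beat_times))
  if (span < 120) stop("record shorter than 2 minutes")
  grid <- seq(min(beat_times), max(beat_times), by = 1 / fs_interp)
  yi <- spline(beat_times, v, xout = grid, method = "fmm")$y
  # linear detrend
  tt <- grid - grid[1]
  fit <- lm.fit(cbind(1, tt), yi)
  yd <- fit$residuals
  ps <- welchPsd(yd, fs_interp, seg_len = round(seg_len_s * fs_interp))
  vres <- var(yd)
  df <- ps$freq[2] - ps$freq[1]
  tot <- sum(ps$power) * df
  ratio <- if (vres > 1e-10) tot / vres else NA_real_
  if (is.finite(ratio) && abs(ratio - 1) > 0.10) {
    warning(sprintf("Parseval check off by %.1f%%", 100 * abs(ratio - 1)))
  }
  structure(list(freq = ps$freq, power = ps$power, var_resampled = vres,
                 parseval_ratio = ratio),
            class = "rrSpectrum")
}

#' @export
print.rrSpectrum <- function(x, ...) {
  cat(sprintf("<rrSpectrum> %d bins, df = %.4g Hz, total power %.1f ms^2\n",
              length(x$freq), x$freq[2] - x$freq[1],
              sum(x$power) * (x$freq[2] - x$freq[1])))
  invisible(x)
}

# trapezoidal integral of the spectrum over [lo, hi] with linear
# interpolation at the band edges
bandIntegral <- function(freq, power, lo, hi) {
  if (hi <= lo) return(0)
  inside <- freq > lo & freq < hi
  f <- freq[inside]; p <- power[inside]
  if (lo >= freq[1] && lo <= freq[length(freq)]) {
    f <- c(lo, f); p <- c(approx(freq, power, xout = lo)$y, p)
  }
  if (hi >= freq[1] && hi <= freq[length(freq)]) {
    f <- c(f, hi); p <- c(p, approx(freq, power, xout = hi)$y)
  }
  if (length(f) < 2L) return(0)
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Band powers of an interval spectrum
#'
#' Trapezoidal integration of the spectral density: total power over
#' \[0, 0.4\] Hz, LF over \[0.04, 0.15) Hz, HF over \[0.15, 0.4\] Hz.
#'
#' @param spec an `rrSpectrum` from [rrPsd()], covering at least 0.4 Hz
#'   with a grid no coarser than 0.01 Hz.
#' @return Named list `tp`, `lf_abs`, `hf_abs` in ms^2.
#' @export
bandPowers <- function(spec) {
  stopifnot(inherits(spec, "rrSpectrum") ||
              is.list(spec) && all(c("freq", "power") %in% names(spec)))
  freq <- spec$freq; power <- spec$power
  if (max(freq) < 0.4) stop("spectrum must cover at least 0.4 Hz")
  if ((freq[2] - freq[1]) > 0.01 + 1e-12) {
    stop("frequency grid coarser than 0.01 Hz")
  }
  if (any(power < 0)) stop("negative spectral density")
  list(tp = bandIntegral(freq, power, 0, 0.4),
       lf_abs = bandIntegral(freq, power, 0.04, 0.15),
       hf_abs = bandIntegral(freq, power, 0.15, 0.4))
}

#' Normalized LF/HF units and their ratio
#'
#' `lf_nu = 100 * lf / (lf + hf)`, `hf_nu = 100 - lf_nu`, and
#' `lf_hf = lf / hf`.  By construction `lf_nu + hf_nu = 100` and
#' `lf_hf = lf_nu / hf_nu`.
#'
#' @param lf_abs,hf_abs absolute band powers in ms^2, not both zero.
#' @return Named list `lf_nu`, `hf_nu`, `lf_hf`; when `hf_abs = 0` the
#'   ratio is `Inf` with attribute `flag = "hf_zero"`.
#' @export
normalizedUnits <- function(lf_abs, hf_abs) {
  if (lf_abs < 0 || hf_abs < 0) stop("band powers must be non-negative")
  if (lf_abs + hf_abs <= 0) stop("LF + HF power is zero")
  lf_nu <- 100 * lf_abs / (lf_abs + hf_abs)
  out <- list(lf_nu = lf_nu, hf_nu = 100 - lf_nu,
              lf_hf = if (hf_abs > 0) lf_abs / hf_abs else Inf)
  if (hf_abs == 0) attr(out, "flag") <- "hf_zero"
  out
}

#' Heart-rhythm coherence ratio
#'
#' Locates the tallest spectral peak in the 0.04-0.26 Hz coherence range,
#' integrates the density over a 0.030 Hz-wide window centred on it
#' (peak power `P`), and returns `CR = P / (TP - P)` where `TP` is the
#' total power over \[0, 0.4\] Hz.  A sine-wave-like ("coherent") heart
#' rhythm concentrates its power in the window and yields a large ratio.
#'
#' @param spec an `rrSpectrum` with positive total power.
#' @return The coherence ratio; `Inf` when the peak window holds all power.
#' @export
coherenceRatio <- function(spec) {
  freq <- spec$freq; power <- spec$power
  tp <- bandIntegral(freq, power, 0, 0.4)
  if (tp <= 1e-10) stop("total power is zero")
  sel <- which(freq >= 0.04 & freq <= 0.26)
  if (!length(sel)) stop("spectrum does not cover the 0.04-0.26 Hz range")
  f0 <- freq[sel[which.max(power[sel])]]
  P <- bandIntegral(freq, power, f0 - 0.015, f0 + 0.015)
  if (P >= tp) return(Inf)
  P / (tp - P)
}

#' Respiration summary statistics
#'
#' @param cycles a [respCycleSeries()] with at least 2 complete cycles.
#' @return Object of class `respStats`: `breathing_rate` (breaths/min,
#'   `60 / mean cycle length`), `mean_insp` and `mean_exp` (s).
#' @export
respStats <- function(cycles) {
  stopifnot(inherits(cycles, "respCycleSeries"))
  cyc <- diff(cycles$trough_times)
  if (length(cyc) < 2L) stop("need at least 2 complete cycles")
  structure(list(breathing_rate = 60 / mean(cyc),
                 mean_insp = mean(cycles$insp_durations),
                 mean_exp = mean(cycles$exp_durations)),
            class = "respStats")
}

#' @export
print.respStats <- function(x, ...) {
  cat(sprintf("<respStats> %.1f breaths/min, insp %.2f s / exp %.2f s\n",
              x$breathing_rate, x$mean_insp, x$mean_exp))
  invisible(x)
}

#' Full HRV metric panel from an interval series
#'
#' Computes SDNN, rMSSD, the Welch spectrum with total/LF/HF powers,
#' normalized units, LF/HF ratio and the coherence ratio in one call.
#'
#' @param intervals an [intervalSeries()] spanning at least 2 minutes.
#' @param beat_times optional beat times (see [rrPsd()]).
#' @return Object of class `hrvMetrics` with fields `sdnn`, `rmssd`, `tp`,
#'   `lf_abs`, `hf_abs`, `lf_nu`, `hf_nu`, `lf_hf`, `cr` (all numeric).
#' @export
hrvMetrics <- function(intervals, beat_times = NULL) {
  spec <- rrPsd(intervals, beat_times)
  bp <- bandPowers(spec)
  nu <- normalizedUnits(bp$lf_abs, bp$hf_abs)
  structure(list(sdnn = sdnn(intervals), rmssd = rmssd(intervals),
                 tp = bp$tp, lf_abs = bp$lf_abs, hf_abs = bp$hf_abs,
                 lf_nu = nu$lf_nu, hf_nu = nu$hf_nu, lf_hf = nu$lf_hf,
                 cr = coherenceRatio(spec)),
            class = "hrvMetrics")
}

#' @export
print.hrvMetrics <- function(x, ...) {
  cat("<hrvMetrics>\n")
  cat(sprintf("  SDNN %.1f ms   rMSSD %.1f ms   TP %.0f ms^2\n",
              x$sdnn, x$rmssd, x$tp))
  cat(sprintf("  LF %.0f ms^2 (%.1f nu)   HF %.0f ms^2 (%.1f nu)   LF/HF %.2f   CR %.2f\n",
              x$lf_abs, x$lf_nu, x$hf_abs, x$hf_nu, x$lf_hf, x$cr))
  invisible(x)
}
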