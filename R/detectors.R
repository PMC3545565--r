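# Event detection: adaptive-threshold R-peak / pulse-peak detection and
# respiration cycle segmentation; interval-series construction with
# artifact rejection.

#' Detected beat event series
#'
#' @param event_times strictly increasing event times in seconds.
#' @param kind `"R_PEAK"` (ECG) or `"PULSE_PEAK"` (PPG).
#' @return Object of class `beatSeries`.
#' @export
beatSeries <- function(event_times, kind = c("R_PEAK", "PULSE_PEAK")) {
  kind <- match.arg(kind)
  event_times <- as.numeric(event_times)
  if (length(event_times) > 1L && any(diff(event_times) <= 0)) {
    stop("event times must be strictly increasing")
  }
  structure(list(event_times = event_times, kind = kind),
            class = "beatSeries")
}

#' @export
print.beatSeries <- function(x, ...) {
  cat(sprintf("<beatSeries> %d %s events", length(x$event_times), x$kind))
  if (length(x$event_times) > 1L) {
    cat(sprintf(" over %.1f s (mean rate %.1f /min)",
                diff(range(x$event_times)),
                60 * (length(x$event_times) - 1) / diff(range(x$event_times))))
  }
  cat("\n")
  invisible(x)
}

#' Interbeat interval series
#'
#' @param intervals positive interval durations in ms, each in (200, 3000).
#' @param kind `"RR"` or `"PP"`.
#' @param times optional time stamps in seconds of the beat ending each
#'   interval (needed for spectral analysis).
#' @param dropped number of intervals removed by artifact rejection.
#' @return Object of class `intervalSeries`.
#' @export
intervalSeries <- function(intervals, kind = c("RR", "PP"), times = NULL,
                           dropped = 0L) {
  kind <- match.arg(kind)
  intervals <- as.numeric(intervals)
  if (any(!is.finite(intervals)) || any(intervals <= 200) || any(intervals >= 3000)) {
    stop("intervals must lie strictly within (200, 3000) ms")
  }
  if (!is.null(times) && length(times) != length(intervals)) {
    stop("times must parallel intervals")
  }
  structure(list(intervals = intervals, kind = kind, times = times,
                 dropped = as.integer(dropped)),
            class = "intervalSeries")
}

#' @export
print.intervalSeries <- function(x, ...) {
  cat(sprintf("<intervalSeries> %d %s intervals, mean %.1f ms (%d dropped)\n",
              length(x$intervals), x$kind, mean(x$intervals), x$dropped))
  invisible(x)
}

#' Respiration cycle series
#'
#' Alternating trough/peak breath landmarks with per-breath inspiration
#' (trough to peak) and expiration (peak to next trough) durations.
#'
#' @param trough_times,peak_times landmark times in seconds; must strictly
#'   alternate trough, peak, trough, ...
#' @param insp_durations,exp_durations per-breath durations in seconds; if
#'   omitted, derived from the landmark times.
#' @return Object of class `respCycleSeries`.
#' @export
respCycleSeries <- function(trough_times, peak_times,
                            insp_durations = NULL, exp_durations = NULL) {
  trough_times <- as.numeric(trough_times)
  peak_times <- as.numeric(peak_times)
  ncyc <- length(trough_times) - 1L
  if (ncyc < 1L || length(peak_times) < ncyc) {
    stop("need at least two troughs with a peak between them")
  }
  peak_times <- peak_times[seq_len(ncyc)]
  if (any(peak_times <= trough_times[seq_len(ncyc)]) ||
      any(peak_times >= trough_times[-1L])) {
    stop("troughs and peaks must alternate strictly in time")
  }
  if (is.null(insp_durations)) insp_durations <- peak_times - trough_times[seq_len(ncyc)]
  if (is.null(exp_durations)) exp_durations <- trough_times[-1L] - peak_times
  structure(list(trough_times = trough_times, peak_times = peak_times,
                 insp_durations = insp_durations, exp_durations = exp_durations),
            class = "respCycleSeries")
}

#' @export
print.respCycleSeries <- function(x, ...) {
  ncyc <- length(x$trough_times) - 1L
  cat(sprintf("<respCycleSeries> %d cycles, mean insp %.2f s / exp %.2f s\n",
              ncyc, mean(x$insp_durations), mean(x$exp_durations)))
  invisible(x)
}

# ---------------------------------------------------------------------------

# local maxima (plateau ties broken toward the earliest sample)
localMaxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# Adaptive-threshold integrate-and-threshold beat detector (Pan-Tompkins
# style).  Shared machinery for ECG R peaks and PPG pulse peaks.
detectBeats <- function(x, band, refine_win, kind) {
  stopifnot(inherits(x, "tsSignal"))
  fs <- x$fs
  if (fs < 128) stop("sampling rate must be >= 128 Hz for beat detection")
  if (duration(x) < 5) stop("record shorter than 5 s")
  raw <- x$samples
  n <- length(raw)
  if (sd(raw) == 0) {
    warning("no beat candidates found; returning empty series")
    out <- beatSeries(numeric(), kind = kind)
    attr(out, "warning") <- "no beats detected"
    return(out)
  }

  bp <- firBandpass(band[1], min(band[2], fs / 2 - 1), fs,
                    max_taps = max(3L, 2L * (n %/% 2L) - 1L))
  y <- applyFirZeroPhase(raw, bp)
  d <- c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1])  # central diff
  sq <- d * d
  wlen <- round(0.150 * fs)
  if (wlen %% 2 == 0) wlen <- wlen + 1
  mwi <- movingAverage(sq, wlen)

  cand <- localMaxima(mwi)
  if (!length(cand) || max(mwi) <= 0) {
    warning("no beat candidates found; returning empty series")
    out <- beatSeries(numeric(), kind = kind)
    attr(out, "warning") <- "no beats detected"
    return(out)
  }
  ct <- (cand - 1) / fs
  cv <- mwi[cand]

  # scale-relative initialisation from the first two seconds
  rpe <- max(mwi[seq_len(min(n, round(2 * fs)))])
  thr <- 0.5 * rpe
  refractory <- 0.2
  accepted <- integer()

  lastT <- function() if (length(accepted)) ct[accepted[length(accepted)]] else -Inf
  meanRR <- function() {
    k <- length(accepted)
    if (k < 3L) return(NA_real_)
    mean(tail(diff(ct[accepted]), 8L))
  }
  acceptBeat <- function(i) {
    rpe <<- 0.125 * cv[i] + 0.875 * rpe
    thr <<- 0.5 * rpe
    accepted <<- c(accepted, i)
  }

  i <- 1L
  while (i <= length(cand)) {
    gap <- ct[i] - lastT()
    if (gap < refractory) {
      # a larger candidate inside the refractory window supersedes the beat
      k <- length(accepted)
      prev_t <- if (k > 1L) ct[accepted[k - 1L]] else -Inf
      if (k && cv[i] > cv[accepted[k]] && ct[i] - prev_t >= refractory) {
        accepted[k] <- i
      }
    } else if (cv[i] >= thr) {
      acceptBeat(i)
    } else if (is.finite(meanRR()) && gap > 1.66 * meanRR()) {
      # search-back: take the largest skipped candidate above half threshold
      win <- which(ct > lastT() + refractory & ct <= ct[i])
      if (length(win)) {
        j <- win[which.max(cv[win])]
        if (cv[j] >= 0.5 * thr) acceptBeat(j)
      }
    }
    i <- i + 1L
  }

  if (!length(accepted)) {
    warning("no beats exceeded the detection threshold")
    out <- beatSeries(numeric(), kind = kind)
    attr(out, "warning") <- "no beats detected"
    return(out)
  }

  # refine each event to the raw-signal maximum near the candidate
  hw <- round(refine_win * fs)
  times <- vapply(cand[accepted], function(ci) {
    lo <- max(1L, ci - hw); hi <- min(n, ci + hw)
    (lo + which.max(raw[lo:hi]) - 2L) / fs
  }, 0)
  times <- sort(unique(times))
  keep <- c(TRUE, diff(times) >= refractory)
  beatSeries(x$t0 + times[keep], kind = kind)
}

#' Detect R peaks in an ECG with an adaptive threshold
#'
#' Pipeline: 5-15 Hz band-pass, differentiation, squaring, 150 ms
#' moving-window integration; candidate local maxima are accepted against an
#' adaptive threshold `thr = 0.5 * rpe` with the running peak estimate
#' updated per beat as `rpe <- 0.125 * peak + 0.875 * rpe`; 200 ms
#' refractory; a search-back at 1.66 times the running RR mean rescues
#' missed beats at half threshold; each event is refined to the raw-signal
#' maximum within +/- 50 ms.  Detection is invariant to positive amplitude
#' scaling.
#'
#' @param ecg a preprocessed ECG [tsSignal()], `fs >= 128` Hz, `>= 5` s.
#' @return A [beatSeries()] of kind `"R_PEAK"`; empty with a warning when no
#'   candidate exists anywhere in the record.
#' @export
detectRPeaks <- function(ecg) {
  detectBeats(ecg, band = c(5, 15), refine_win = 0.050, kind = "R_PEAK")
}

#' Detect pulse peaks in a PPG
#'
#' Same adaptive-threshold machinery as [detectRPeaks()] with a 0.5-8 Hz
#' detection band and a +/- 100 ms refinement window, matching the smoother
#' pulse upstroke.
#'
#' @param ppg a preprocessed PPG [tsSignal()].
#' @return A [beatSeries()] of kind `"PULSE_PEAK"`.
#' @export
detectPulsePeaks <- function(ppg) {
  detectBeats(ppg, band = c(0.5, 8), refine_win = 0.100, kind = "PULSE_PEAK")
}

# prominence of a local maximum: height above the higher of the two valley
# minima reached before a taller sample is met on each side
peakProminence <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    lmin <- h; j <- i
    while (j > 1L) { j <- j - 1L; if (y[j] > h) break; lmin <- min(lmin, y[j]) }
    rmin <- h; j <- i
    while (j < length(y)) { j <- j + 1L; if (y[j] > h) break; rmin <- min(rmin, y[j]) }
    h - max(lmin, rmin)
  }, 0)
}

#' Segment a respiration signal into breath cycles
#'
#' The signal is smoothed with a 1 s moving average; alternating local
#' extrema with prominence of at least 20% of the signal's inter-quartile
#' range and cycles of at least 1.5 s are kept.  Convention: the rising
#' segment (trough to peak) is inspiration; pass an inverted signal for raw
#' thermistor traces whose output rises during exhalation.  Incomplete
#' first/last cycles are dropped.
#'
#' @param resp a preprocessed respiration [tsSignal()] covering at least two
#'   complete breaths.
#' @return A [respCycleSeries()].
#' @export
detectRespCycles <- function(resp) {
  stopifnot(inherits(resp, "tsSignal"))
  fs <- resp$fs
  w <- round(fs)
  if (w %% 2 == 0) w <- w + 1
  y <- if (w >= 3 && w < length(resp$samples)) movingAverage(resp$samples, w) else resp$samples
  minprom <- 0.2 * diff(quantile(y, c(0.25, 0.75), names = FALSE))
  mindist <- round(0.75 * 1.5 * fs)          # extrema of one cycle >= 1.5 s apart

  pickExtrema <- function(v) {
    idx <- localMaxima(v)
    idx <- idx[peakProminence(v, idx) >= minprom]
    # enforce minimum spacing, keeping the taller of close pairs
    if (length(idx) > 1L) {
      keep <- idx[1L]
      for (i in idx[-1L]) {
        if (i - keep[length(keep)] < mindist) {
          if (v[i] > v[keep[length(keep)]]) keep[length(keep)] <- i
        } else keep <- c(keep, i)
      }
      idx <- keep
    }
    idx
  }
  peaks <- pickExtrema(y)
  troughs <- pickExtrema(-y)
  if (length(peaks) < 2L || length(troughs) < 2L) {
    stop("fewer than two complete respiration cycles detected")
  }

  # interleave and enforce strict alternation (keep the extreme sample)
  ev <- rbind(data.frame(i = peaks, type = "peak"),
              data.frame(i = troughs, type = "trough"))
  ev <- ev[order(ev$i), ]
  keep <- ev[1L, , drop = FALSE]
  for (r in 2:nrow(ev)) {
    lastr <- nrow(keep)
    if (ev$type[r] == keep$type[lastr]) {
      better <- if (ev$type[r] == "peak") y[ev$i[r]] > y[keep$i[lastr]] else
        y[ev$i[r]] < y[keep$i[lastr]]
      if (better) keep[lastr, ] <- ev[r, ]
    } else keep <- rbind(keep, ev[r, ])
  }
  # trim to start at a trough and end at a trough (complete cycles only)
  first <- which(keep$type == "trough")[1L]
  if (is.na(first)) stop("fewer than two complete respiration cycles detected")
  keep <- keep[first:nrow(keep), ]
  lastt <- max(which(keep$type == "trough"))
  keep <- keep[seq_len(lastt), ]
  tr <- keep$i[keep$type == "trough"]
  pk <- keep$i[keep$type == "peak"]
  if (length(tr) < 3L) stop("fewer than two complete respiration cycles detected")
  # refine landmark positions on a lightly smoothed signal: the 1 s average
  # used for extremum picking biases asymmetric cycles
  wf <- max(3L, round(0.1 * fs)); if (wf %% 2L == 0L) wf <- wf + 1L
  yf <- if (wf < length(resp$samples)) movingAverage(resp$samples, wf) else y
  hw <- round(0.5 * fs)
  refine <- function(idx, sign) {
    vapply(idx, function(i) {
      lo <- max(1L, i - hw); hi <- min(length(yf), i + hw)
      lo + which.max(sign * yf[lo:hi]) - 1L
    }, 0)
  }
  tr <- refine(tr, -1)
  pk <- refine(pk, +1)
  if (any(diff(tr) <= 0) || any(pk <= tr[-length(tr)]) || any(pk >= tr[-1L])) {
    # refinement broke alternation (pathological input); fall back
    tr <- keep$i[keep$type == "trough"]; pk <- keep$i[keep$type == "peak"]
  }
  respCycleSeries(resp$t0 + (tr - 1) / fs, resp$t0 + (pk - 1) / fs)
}

#' Beat events to interbeat intervals with artifact rejection
#'
#' Successive differences of the event times, in ms.  Rejection rules:
#' intervals outside (200, 3000) ms are dropped; an interval below 200 ms
#' marks a spurious extra beat, so both intervals sharing that beat are
#' dropped; intervals deviating from the running median of the surrounding
#' 11 intervals by more than 30% are dropped.  The number of rejected
#' intervals is recorded in the result.
#'
#' @param beats a [beatSeries()] with at least 3 events.
#' @return An [intervalSeries()] with `times` set to the time of the beat
#'   ending each surviving interval and `dropped` counting rejections.
#' @export
beatsToIntervals <- function(beats) {
  stopifnot(inherits(beats, "beatSeries"))
  tt <- beats$event_times
  if (length(tt) < 3L) stop("need at least 3 beat events")
  d <- diff(tt) * 1000
  end_t <- tt[-1L]
  short <- d <= 200
  bad <- short | d >= 3000
  # an interval after a too-short one shares the spurious beat
  bad <- bad | c(FALSE, short[-length(short)])
  k <- min(11L, length(d))
  if (k %% 2L == 0L) k <- k - 1L
  med <- runmed(d, k = k, endrule = "median")
  bad <- bad | abs(d - med) > 0.30 * med
  dropped <- sum(bad)
  if (sum(!bad) < 2L) stop("fewer than 2 intervals survive artifact rejection")
  intervalSeries(d[!bad], kind = if (beats$kind == "R_PEAK") "RR" else "PP",
                 times = end_t[!bad], dropped = dropped)
}
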