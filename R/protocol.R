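# The three-step biofeedback protocol: resonance-frequency search (paced
# breathing sweep), stress assessment, and resonance-frequency training
# with adherence tracking.

#' One paced-breathing sweep epoch
#'
#' @param pacing_frequency paced breathing frequency in breaths/min.
#' @param intervals the epoch's [intervalSeries()] (with `times`).
#' @param beat_times beat times in seconds; taken from `intervals$times`
#'   when omitted.
#' @param resp optional [respCycleSeries()] of the measured breaths; when
#'   absent, breath windows are derived from the pacing frequency.
#' @return Object of class `sweepEpoch`.
#' @export
sweepEpoch <- function(pacing_frequency, intervals, beat_times = NULL,
                       resp = NULL) {
  stopifnot(inherits(intervals, "intervalSeries"))
  if (is.null(beat_times)) beat_times <- intervals$times
  if (is.null(beat_times)) stop("beat times required")
  structure(list(pacing_frequency = pacing_frequency, intervals = intervals,
                 beat_times = beat_times, resp = resp),
            class = "sweepEpoch")
}

# nominal breath windows from a pacing frequency, spanning the beat record
nominalCycles <- function(pacing_frequency, beat_times) {
  period <- 60 / pacing_frequency
  t0 <- min(beat_times); t1 <- max(beat_times)
  troughs <- seq(t0, t1, by = period)
  if (length(troughs) < 3L) stop("epoch too short for breath windows")
  respCycleSeries(troughs, head(troughs, -1) + period / 2)
}

#' Per-breath respiratory sinus arrhythmia amplitude
#'
#' For each complete breath (trough to next trough), the RSA amplitude is
#' the peak-to-trough range `max(RR) - min(RR)` of the intervals whose
#' ending beat falls inside the breath; the result is the mean over breaths
#' containing at least 3 beats.  Invariant to adding a constant to all
#' intervals.
#'
#' @param intervals an [intervalSeries()].
#' @param beat_times beat times (s) of the interval endpoints; defaults to
#'   `intervals$times`.
#' @param cycles a [respCycleSeries()] delimiting the breaths; at least 5
#'   qualifying breaths are required.
#' @return Mean per-breath RSA amplitude in ms.
#' @export
rsaAmplitude <- function(intervals, beat_times = NULL, cycles) {
  stopifnot(inherits(intervals, "intervalSeries"),
            inherits(cycles, "respCycleSeries"))
  if (is.null(beat_times)) beat_times <- intervals$times
  if (is.null(beat_times)) stop("beat times required")
  v <- intervals$intervals
  tr <- cycles$trough_times
  amps <- numeric()
  for (k in seq_len(length(tr) - 1L)) {
    sel <- beat_times >= tr[k] & beat_times < tr[k + 1L]
    if (sum(sel) >= 3L) amps <- c(amps, max(v[sel]) - min(v[sel]))
  }
  if (length(amps) < 5L) {
    stop("need at least 5 complete breaths with >= 3 beats each, got ",
         length(amps))
  }
  mean(amps)
}

#' Paced-breathing guide waveform
#'
#' Raised-cosine inhale/exhale guide in \[0, 1\] with equal halves at the
#' requested pacing period, suitable for driving a breathing pacer display.
#'
#' @param frequency pacing frequency in breaths/min, within \[4, 7\].
#' @param duration guide length in seconds.
#' @param fs sampling rate in Hz.
#' @return A [tsSignal()] of kind RESP.
#' @export
pacingWaveform <- function(frequency, duration, fs = 32) {
  if (frequency < 4 || frequency > 7) {
    stop("pacing frequency must lie within [4, 7] breaths/min")
  }
  if (duration <= 0) stop("duration must be positive")
  tt <- (0:(round(duration * fs) - 1)) / fs
  tsSignal(0.5 - 0.5 * cos(2 * pi * frequency / 60 * tt),
           fs = fs, kind = "RESP", units = "normalized")
}

#' Resonance-frequency sweep
#'
#' Measures the RSA gain of each paced epoch via [rsaAmplitude()] and
#' selects the resonant breathing frequency as the grid frequency with the
#' maximum gain; ties break toward the lowest (slowest) frequency.
#'
#' @param epochs list of [sweepEpoch()]s, one per grid frequency, each
#'   spanning at least 2 minutes of beats.
#' @param grid the pacing grid in breaths/min (default 4 to 7 by 0.5);
#'   every grid frequency must appear among the epochs.
#' @return Object of class `resonanceSweepResult`: `per_frequency_gain`
#'   (named numeric, ms) and `resonant_frequency` (breaths/min).
#' @export
resonanceSweep <- function(epochs, grid = seq(4, 7, by = 0.5)) {
  freqs <- vapply(epochs, function(e) e$pacing_frequency, 0)
  missing <- setdiff(round(grid, 6), round(freqs, 6))
  if (length(missing)) {
    stop("sweep grid frequency missing: ", paste(missing, collapse = ", "))
  }
  ord <- order(freqs)
  epochs <- epochs[ord]; freqs <- freqs[ord]
  gains <- vapply(epochs, function(e) {
    if (diff(range(e$beat_times)) < 120) {
      stop(sprintf("epoch at %.1f b/min shorter than 2 min", e$pacing_frequency))
    }
    cyc <- if (!is.null(e$resp)) e$resp else
      nominalCycles(e$pacing_frequency, e$beat_times)
    rsaAmplitude(e$intervals, e$beat_times, cyc)
  }, 0)
  best <- which(gains >= max(gains) - 1e-12)[1L]   # tie -> lowest frequency
  structure(list(per_frequency_gain = setNames(gains, freqs),
                 resonant_frequency = freqs[best]),
            class = "resonanceSweepResult")
}

#' @export
print.resonanceSweepResult <- function(x, ...) {
  cat(sprintf("<resonanceSweepResult> resonant frequency %.1f breaths/min\n",
              x$resonant_frequency))
  g <- x$per_frequency_gain
  cat(paste(sprintf("  %4s b/min: %6.1f ms", names(g), g), collapse = "\n"), "\n")
  invisible(x)
}

# analyse one ECG(+resp) epoch; metrics = FALSE skips the spectral panel
analyseEpoch <- function(ecg, resp = NULL, metrics = TRUE) {
  clean <- preprocessSignal(ecg)
  beats <- detectRPeaks(clean)
  ints <- beatsToIntervals(beats)
  list(metrics = if (metrics) hrvMetrics(ints) else NULL, intervals = ints,
       cycles = if (!is.null(resp)) detectRespCycles(bandpassFir(resp)) else NULL)
}

#' Run a full biofeedback session
#'
#' Executes the three protocol steps on a recorded (or simulated) session:
#' Step 1 finds the individual's resonant breathing frequency from the
#' paced sweep; Step 2 assesses the pre-training stress level from HRV;
#' Step 3 analyses the training epoch, re-assesses, and measures adherence
#' as the fraction of training breaths whose instantaneous rate lies within
#' 0.5 breaths/min of the resonant pacing frequency.  Deterministic given
#' its inputs.
#'
#' @param config a [sessionConfig()].
#' @param signals list with elements:
#'   * `sweep`: list of `list(frequency, ecg, resp)` per grid frequency
#'     (`resp` optional; raw [tsSignal()]s),
#'   * `pre`: `list(ecg, resp)` pre-training epoch,
#'   * `post`: `list(ecg, resp)` training epoch.
#'   The respiration channel is required.
#' @return Object of class `sessionReport` with pre/post `hrvMetrics`,
#'   pre/post `stressAssessment`, `resonant_frequency`,
#'   `per_frequency_gain` and `adherence`.
#' @export
runBiofeedbackSession <- function(config, signals) {
  stopifnot(inherits(config, "sessionConfig"))
  step <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s: %s", label, conditionMessage(e)), call. = FALSE)
    })
  }
  res <- step("step 1 (resonance sweep)", {
    if (is.null(signals$pre$resp) || is.null(signals$post$resp)) {
      stop("respiration channel required")
    }
    epochs <- lapply(signals$sweep, function(s) {
      ep <- analyseEpoch(s$ecg, s$resp, metrics = FALSE)
      sweepEpoch(s$frequency, ep$intervals, resp = ep$cycles)
    })
    resonanceSweep(epochs, grid = config$sweep_frequencies)
  })
  pre <- step("step 2 (stress assessment)", analyseEpoch(signals$pre$ecg))
  pre_assess <- assessStress(pre$metrics)
  post <- step("step 3 (RFT training)", {
    a <- analyseEpoch(signals$post$ecg, signals$post$resp)
    rate <- 60 / diff(a$cycles$trough_times)
    a$adherence <- mean(abs(rate - res$resonant_frequency) <= 0.5)
    a
  })
  structure(list(resonant_frequency = res$resonant_frequency,
                 per_frequency_gain = res$per_frequency_gain,
                 pre = pre$metrics, post = post$metrics,
                 pre_assessment = pre_assess,
                 post_assessment = assessStress(post$metrics),
                 adherence = post$adherence),
            class = "sessionReport")
}

#' @export
print.sessionReport <- function(x, ...) {
  cat(sprintf("<sessionReport> resonant frequency %.1f b/min, adherence %.0f%%\n",
              x$resonant_frequency, 100 * x$adherence))
  cat(sprintf("  pre:  SDNN %5.1f ms  LF/HF %5.2f  -> %s / %s\n",
              x$pre$sdnn, x$pre$lf_hf,
              x$pre_assessment$sdnn_level, x$pre_assessment$balance))
  cat(sprintf("  post: SDNN %5.1f ms  LF/HF %5.2f  -> %s / %s\n",
              x$post$sdnn, x$post$lf_hf,
              x$post_assessment$sdnn_level, x$post_assessment$balance))
  invisible(x)
}
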