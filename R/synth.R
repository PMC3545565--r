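# Synthetic cardiorespiratory signal generator with ground-truth
# annotations: RR series from an RSA model with a tunable resonance curve
# (IPFM beat placement), Gaussian-sum ECG morphology, piecewise-smooth
# respiration, and a cohort builder.

#' Respiratory-sinus-arrhythmia model with a resonance curve
#'
#' The per-frequency RSA gain (peak-to-trough RR modulation, ms) follows a
#' unimodal Gaussian-shaped curve centred on the subject's resonance
#' frequency: `gain(f) = peak_gain * exp(-(f - resonance)^2 / (2 width^2))`.
#'
#' @param mean_rr mean RR interval in ms (default 800, i.e. 75 bpm).
#' @param resonance_freq resonance frequency in breaths/min (default 6,
#'   about 0.1 Hz).
#' @param peak_gain RSA gain at resonance, ms peak-to-trough (default 100).
#' @param curve_width Gaussian width of the gain curve in breaths/min
#'   (default 0.8, so grid neighbours 0.5 b/min away sit about 20% lower).
#' @param rr_noise_sd per-beat Gaussian interval noise, ms (default 10).
#' @return Object of class `rsaModel`.
#' @export
rsaModel <- function(mean_rr = 800, resonance_freq = 6, peak_gain = 100,
                     curve_width = 0.8, rr_noise_sd = 10) {
  stopifnot(mean_rr > 200, resonance_freq > 0, peak_gain >= 0,
            curve_width > 0, rr_noise_sd >= 0)
  structure(list(mean_rr = mean_rr, resonance_freq = resonance_freq,
                 peak_gain = peak_gain, curve_width = curve_width,
                 rr_noise_sd = rr_noise_sd),
            class = "rsaModel")
}

#' RSA gain of a model at a breathing frequency
#' @param model an [rsaModel()].
#' @param freq breathing frequency in breaths/min.
#' @return Gain in ms (peak-to-trough RR modulation).
#' @export
rsaGainAt <- function(model, freq) {
  stopifnot(inherits(model, "rsaModel"))
  if (any(!is.finite(freq)) || any(freq <= 0)) stop("undefined gain at this frequency")
  model$peak_gain * exp(-(freq - model$resonance_freq)^2 / (2 * model$curve_width^2))
}

#' Noise specification for synthetic signals
#'
#' @param powerline_amp 60 Hz powerline amplitude (signal units).
#' @param baseline_amp,baseline_freq sinusoidal baseline wander amplitude
#'   and frequency (`< 0.5` Hz).
#' @param impulse_rate single-sample impulse events per minute.
#' @param impulse_amp impulse amplitude (signed at random).
#' @param snr_db if finite, additive white Gaussian noise at this
#'   signal-to-noise ratio (dB) relative to the clean signal power.
#' @return Object of class `noiseSpec`.
#' @export
noiseSpec <- function(powerline_amp = 0, baseline_amp = 0, baseline_freq = 0.3,
                      impulse_rate = 0, impulse_amp = 0, snr_db = Inf) {
  stopifnot(powerline_amp >= 0, baseline_amp >= 0, baseline_freq < 0.5,
            impulse_rate >= 0, impulse_amp >= 0)
  structure(list(powerline_amp = powerline_amp, baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq, impulse_rate = impulse_rate,
                 impulse_amp = impulse_amp, snr_db = snr_db),
            class = "noiseSpec")
}

#' Synthesise an RR interval series under paced breathing
#'
#' The instantaneous interval follows
#' `RR(t) = mean_rr + gain(f_b)/2 * sin(2 pi f_b t)` with `f_b` the paced
#' breathing frequency; beats are placed by integrate-to-threshold (IPFM)
#' on the instantaneous rate `1/RR(t)`, so beat times and the interval
#' series stay mutually consistent.  Gaussian noise of SD `rr_noise_sd` is
#' then added to each interval and the beat times rebuilt cumulatively.
#'
#' @param model an [rsaModel()].
#' @param breathing_freq paced breathing frequency in breaths/min.
#' @param duration record length in seconds, `>= 60`.
#' @param seed optional integer seed; the output is reproducible under it.
#' @return List `intervals` (an [intervalSeries()] with `times`) and
#'   `beat_times` (seconds).
#' @export
synthRr <- function(model, breathing_freq, duration, seed = NULL) {
  stopifnot(inherits(model, "rsaModel"))
  if (duration < 60) stop("duration must be at least 60 s")
  gain <- rsaGainAt(model, breathing_freq)
  if (!is.null(seed)) set.seed(seed)
  f_b <- breathing_freq / 60
  dt <- 1e-3
  tg <- seq(0, duration, by = dt)
  rr_ms <- model$mean_rr + gain / 2 * sin(2 * pi * f_b * tg)
  haz <- cumsum(1000 / rr_ms) * dt          # integrated instantaneous rate
  nb <- floor(max(haz))
  if (nb < 3L) stop("record too short for beat placement")
  beats <- approx(haz, tg, xout = seq_len(nb))$y
  ints <- diff(beats) * 1000
  if (model$rr_noise_sd > 0) {
    ints <- ints + rnorm(length(ints), 0, model$rr_noise_sd)
    ints <- pmin(pmax(ints, 250), 2900)     # keep physiological
    beats <- c(beats[1L], beats[1L] + cumsum(ints) / 1000)
  }
  list(intervals = intervalSeries(ints, kind = "RR", times = beats[-1L]),
       beat_times = beats)
}

# P-QRS-T Gaussian-sum template: offsets (s), amplitudes (mV), widths (s)
ecgTemplate <- function(tt) {
  off <- c(-0.20, -0.030, 0.000, 0.030, 0.25)
  amp <- c(0.12, -0.10, 1.00, -0.15, 0.30)
  sig <- c(0.025, 0.010, 0.012, 0.010, 0.060)
  y <- numeric(length(tt))
  for (k in seq_along(off)) {
    y <- y + amp[k] * exp(-(tt - off[k])^2 / (2 * sig[k]^2))
  }
  y
}

#' Render a synthetic ECG from beat times
#'
#' Each beat is rendered as a Gaussian-sum P-QRS-T template (R amplitude
#' 1 mV) centred on its time; noise per the [noiseSpec()] is added
#' afterwards.  Morphological fidelity suffices for detector validation,
#' not for clinical realism.
#'
#' @param beat_times strictly increasing R times in seconds, no two closer
#'   than 200 ms.
#' @param fs sampling rate in Hz, `>= 128`.
#' @param noise a [noiseSpec()].
#' @param duration record length in seconds (default: last beat + 0.5 s).
#' @param seed optional integer seed for the stochastic noise components.
#' @return List `signal` (a [tsSignal()], kind ECG) and `truth`
#'   (the beat times).
#' @export
synthEcg <- function(beat_times, fs = 512, noise = noiseSpec(),
                     duration = NULL, seed = NULL) {
  if (!length(beat_times)) stop("empty beat list")
  if (fs < 128) stop("fs must be >= 128 Hz")
  if (length(beat_times) > 1L && any(diff(beat_times) < 0.2)) {
    stop("beats closer than 200 ms apart")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration)) duration <- max(beat_times) + 0.5
  n <- round(duration * fs)
  tt <- (0:(n - 1)) / fs
  y <- numeric(n)
  half <- round(0.45 * fs)
  for (bt in beat_times) {
    ci <- round(bt * fs) + 1
    lo <- max(1, ci - half); hi <- min(n, ci + half)
    if (lo > n || hi < 1) next
    idx <- lo:hi
    y[idx] <- y[idx] + ecgTemplate(tt[idx] - bt)
  }
  clean_var <- var(y)
  if (noise$powerline_amp > 0) {
    y <- y + noise$powerline_amp * sin(2 * pi * 60 * tt)
  }
  if (noise$baseline_amp > 0) {
    y <- y + noise$baseline_amp * sin(2 * pi * noise$baseline_freq * tt)
  }
  if (noise$impulse_rate > 0) {
    k <- rpois(1, noise$impulse_rate * duration / 60)
    if (k > 0) {
      at <- sample.int(n, k)
      y[at] <- y[at] + noise$impulse_amp * (2 * rbinom(k, 1, 0.5) - 1)
    }
  }
  if (is.finite(noise$snr_db)) {
    nsd <- sqrt(clean_var / 10^(noise$snr_db / 10))
    y <- y + rnorm(n, 0, nsd)
  }
  list(signal = tsSignal(y, fs = fs, kind = "ECG"),
       truth = beat_times)
}

#' Synthesise a respiration waveform with known cycle landmarks
#'
#' Piecewise raised-cosine breathing cycle: the signal rises from trough to
#' peak over the inspiratory fraction of the cycle and falls back over the
#' remainder.  The true trough/peak times are returned alongside.
#'
#' @param rate breathing rate in breaths/min, within \[2, 30\].
#' @param insp_frac inspiratory fraction of the cycle, in (0.1, 0.9).
#' @param fs sampling rate in Hz.
#' @param duration record length in seconds.
#' @param noise optional [noiseSpec()] (only `snr_db` is used).
#' @param seed optional integer seed.
#' @return List `signal` (a [tsSignal()], kind RESP) and `truth` (a
#'   [respCycleSeries()] of the complete cycles).
#' @export
synthResp <- function(rate, insp_frac = 0.5, fs = 32, duration = 60,
                      noise = NULL, seed = NULL) {
  if (rate < 2 || rate > 30) stop("breathing rate must lie within [2, 30] b/min")
  if (insp_frac <= 0.1 || insp_frac >= 0.9) stop("insp_frac must lie in (0.1, 0.9)")
  if (!is.null(seed)) set.seed(seed)
  period <- 60 / rate
  n <- round(duration * fs)
  tt <- (0:(n - 1)) / fs
  ph <- (tt %% period) / period             # cycle phase, troughs at 0
  y <- ifelse(ph < insp_frac,
              0.5 - 0.5 * cos(pi * ph / insp_frac),
              0.5 + 0.5 * cos(pi * (ph - insp_frac) / (1 - insp_frac)))
  if (!is.null(noise) && is.finite(noise$snr_db)) {
    y <- y + rnorm(n, 0, sqrt(var(y) / 10^(noise$snr_db / 10)))
  }
  ncyc <- floor(duration / period - 1e-9)
  if (ncyc < 1L) stop("duration too short for one complete cycle")
  troughs <- (0:ncyc) * period
  troughs <- troughs[troughs <= duration + 1e-9]
  peaks <- head(troughs, -1) + insp_frac * period
  list(signal = tsSignal(y, fs = fs, kind = "RESP"),
       truth = respCycleSeries(troughs, peaks))
}

#' Generate a synthetic three-group study cohort
#'
#' Builds per-subject interbeat recordings (beat times + RR series, with
#' the generating parameters as truth) for three groups emulating a
#' baseline group and a stressed group before and after resonance-breathing
#' training.  Each group profile fixes the target SDNN, the free-breathing
#' rate and the RSA gain at that rate; per-beat noise is solved so the
#' total interval SD hits the target, and subjects jitter around the
#' profile by `subject_cv`.
#'
#' @param n_per_group subjects per group, `>= 1`.
#' @param group_profiles named list (`BL`, `PRE_RFT`, `POST_RFT`) of lists
#'   with `sdnn` (ms), `breathing_rate` (b/min), `rsa_gain` (ms at that
#'   rate), `mean_rr` (ms); defaults emulate group mean SDNN of about
#'   56 / 28 / 55 ms at breathing rates 12.2 / 19.3 / 13.5 b/min.
#' @param seed integer seed; the dataset is deterministic under it.
#' @param duration per-subject record length in seconds (default 300).
#' @param subject_cv between-subject coefficient of variation (default 0.05).
#' @return Named list of groups; each group is a list of subjects, each a
#'   list `intervals`, `beat_times`, `truth` (generating parameters).
#' @export
makeCohort <- function(n_per_group,
                       group_profiles = defaultGroupProfiles(),
                       seed = 1L, duration = 300, subject_cv = 0.05) {
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  need <- c("BL", "PRE_RFT", "POST_RFT")
  if (!all(need %in% names(group_profiles))) {
    stop("group_profiles must contain BL, PRE_RFT, POST_RFT")
  }
  set.seed(seed)
  out <- lapply(group_profiles[need], function(p) {
    lapply(seq_len(n_per_group), function(i) {
      jit <- function(v) v * (1 + rnorm(1, 0, subject_cv))
      sdnn_t <- jit(p$sdnn)
      gain <- jit(p$rsa_gain)
      noise_sd <- sqrt(max(1, sdnn_t^2 - gain^2 / 8))
      m <- rsaModel(mean_rr = jit(p$mean_rr), resonance_freq = 5.5,
                    peak_gain = gain, curve_width = 20,  # flat: gain holds at p$breathing_rate
                    rr_noise_sd = noise_sd)
      rec <- synthRr(m, breathing_freq = p$breathing_rate, duration = duration)
      rec$truth <- list(sdnn = sdnn_t, breathing_rate = p$breathing_rate,
                        rsa_gain = gain, mean_rr = m$mean_rr,
                        rr_noise_sd = noise_sd)
      rec
    })
  })
  attr(out, "seed") <- seed
  out
}

#' Synthesise a complete biofeedback session recording
#'
#' Builds the signal set consumed by [runBiofeedbackSession()]: one paced
#' sweep epoch per grid frequency (ECG + respiration), a pre-training
#' epoch in a stressed regime (low RR variability, slow sympathetic-style
#' 0.1 Hz modulation), and a training epoch breathing at the model's
#' resonance frequency with full RSA gain.
#'
#' @param config a [sessionConfig()].
#' @param model an [rsaModel()] describing the subject; its
#'   `resonance_freq` drives the sweep's true optimum.
#' @param stressed_sdnn target pre-training SDNN in ms (default 28).
#' @param trained_sdnn target training-epoch SDNN in ms (default 55).
#' @param fs_ecg,fs_resp sampling rates for the rendered channels.
#' @param sweep_epoch_s sweep epoch length in seconds (default 130).
#' @param seed integer seed.
#' @return List `sweep`, `pre`, `post` as expected by
#'   [runBiofeedbackSession()], plus `truth` (the generating parameters).
#' @export
synthSession <- function(config, model = rsaModel(), stressed_sdnn = 28,
                         trained_sdnn = 55, fs_ecg = 256, fs_resp = 32,
                         sweep_epoch_s = 130, seed = 1L) {
  stopifnot(inherits(config, "sessionConfig"), inherits(model, "rsaModel"))
  set.seed(seed)
  renderEpoch <- function(rr_model, pace_bpm, resp_rate, dur) {
    rr <- synthRr(rr_model, breathing_freq = pace_bpm, duration = dur)
    ecg <- synthEcg(rr$beat_times, fs = fs_ecg, duration = dur)$signal
    resp <- synthResp(resp_rate, fs = fs_resp, duration = dur)$signal
    list(ecg = ecg, resp = resp)
  }
  sweep <- lapply(config$sweep_frequencies, function(f) {
    ep <- renderEpoch(model, f, f, sweep_epoch_s)
    list(frequency = f, ecg = ep$ecg, resp = ep$resp)
  })
  # stressed: little RSA, modest slow (0.1 Hz) modulation, low overall SD
  pre_model <- rsaModel(mean_rr = model$mean_rr,
                        resonance_freq = model$resonance_freq,
                        peak_gain = stressed_sdnn * sqrt(8) * 0.6,
                        curve_width = 20,
                        rr_noise_sd = stressed_sdnn * 0.8)
  pre <- renderEpoch(pre_model, 6, 19, config$epoch_length)
  # trained: breathing at resonance, full RSA gain
  post_gain <- trained_sdnn * sqrt(8) * 0.9
  post_model <- rsaModel(mean_rr = model$mean_rr,
                         resonance_freq = model$resonance_freq,
                         peak_gain = post_gain, curve_width = model$curve_width,
                         rr_noise_sd = sqrt(max(1, trained_sdnn^2 - post_gain^2 / 8)))
  post <- renderEpoch(post_model, model$resonance_freq,
                      model$resonance_freq, config$epoch_length)
  list(sweep = sweep, pre = pre, post = post,
       truth = list(resonance_freq = model$resonance_freq,
                    stressed_sdnn = stressed_sdnn,
                    trained_sdnn = trained_sdnn))
}

#' Default cohort group profiles
#'
#' Emulates the study conditions of a three-group comparison: a non-stressed
#' baseline group (SDNN about 56 ms, 12.2 breaths/min), a stressed pre-training
#' group (SDNN about 28 ms, rapid shallow breathing at 19.3 b/min, low RSA),
#' and the same group after resonance training (SDNN about 55 ms).
#'
#' @return Named list of group profiles for [makeCohort()].
#' @export
defaultGroupProfiles <- function() {
  list(BL = list(sdnn = 56.4, breathing_rate = 12.2, rsa_gain = 40, mean_rr = 800),
       PRE_RFT = list(sdnn = 27.8, breathing_rate = 19.3, rsa_gain = 10, mean_rr = 750),
       POST_RFT = list(sdnn = 55.3, breathing_rate = 13.5, rsa_gain = 40, mean_rr = 810))
}
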