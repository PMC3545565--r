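# shared fixtures: small synthetic records built in code

# fraction of true events matched by a detection within +/- win seconds
matchRate <- function(truth, detected, win = 0.05) {
  if (!length(truth)) return(NA_real_)
  if (!length(detected)) return(0)
  mean(vapply(truth, function(t) min(abs(detected - t)) <= win, TRUE))
}

# clean rendered ECG with ground truth at a given heart rate
cleanEcg <- function(hr_bpm = 70, duration = 60, fs = 512, gain = 0) {
  m <- rsaModel(mean_rr = 60000 / hr_bpm, peak_gain = gain, rr_noise_sd = 0)
  rr <- synthRr(m, breathing_freq = 6, duration = duration)
  synthEcg(rr$beat_times, fs = fs, duration = duration)
}

# power of x in a band around f0 (relative bandwidth 20%)
tonePower <- function(x, f0, fs) {
  n <- length(x)
  X <- Mod(stats::fft(x))^2 / n
  fr <- (seq_len(n) - 1) * fs / n
  sum(X[fr > 0.8 * f0 & fr < 1.2 * f0])
}
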