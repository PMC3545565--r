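test_that("R-peak detection is exact on clean synthetic ECG", {
  e <- cleanEcg(70, 60)
  det <- detectRPeaks(preprocessSignal(e$signal))
  expect_equal(length(det$event_times), length(e$truth), tolerance = 0.02)
  expect_equal(matchRate(e$truth, det$event_times, win = 0.020), 1)
})

test_that("clean detection rate is 100% across 40-180 bpm", {
  for (hr in c(40, 90, 140, 180)) {
    e <- cleanEcg(hr, 60)
    det <- detectRPeaks(preprocessSignal(e$signal))
    expect_equal(matchRate(e$truth, det$event_times, win = 0.05), 1,
                 info = paste("heart rate", hr))
  }
})

test_that("R-peak detection is invariant to amplitude scaling", {
  e <- cleanEcg(65, 60)
  s2 <- e$signal; s2$samples <- s2$samples * 37.5
  d1 <- detectRPeaks(preprocessSignal(e$signal))
  d2 <- detectRPeaks(preprocessSignal(s2))
  expect_identical(d1$event_times, d2$event_times)
})

test_that("degenerate ECG inputs are handled explicitly", {
  flat <- tsSignal(rep(0, 512 * 10), fs = 512, kind = "ECG")
  expect_warning(out <- detectRPeaks(flat), "no beat")
  expect_length(out$event_times, 0)
  expect_error(detectRPeaks(tsSignal(rnorm(512 * 2), 512, "ECG")), "5 s")
  expect_error(detectRPeaks(tsSignal(rnorm(600), 100, "ECG")), "128 Hz")
})

test_that("pulse-peak detection recovers the generating RR series", {
  m <- rsaModel(mean_rr = 1000, peak_gain = 0, rr_noise_sd = 0)
  rp <- synthRr(m, 6, 60)
  fs <- 128
  tt <- (0:(60 * fs - 1)) / fs
  y <- numeric(length(tt))
  for (bt in rp$beat_times) {      # smooth low-pass pulse train
    idx <- which(abs(tt - bt - 0.15) < 0.4)
    y[idx] <- y[idx] + exp(-(tt[idx] - bt - 0.15)^2 / (2 * 0.08^2))
  }
  ppg <- tsSignal(y, fs = fs, kind = "PPG")
  det <- detectPulsePeaks(ppg)
  expect_equal(det$kind, "PULSE_PEAK")
  expect_equal(length(det$event_times), length(rp$beat_times), tolerance = 0.02)
  pp <- beatsToIntervals(det)
  rr_true <- diff(rp$beat_times) * 1000
  expect_lt(mean(abs(pp$intervals - mean(rr_true))), 10)
  expect_warning(out <- detectPulsePeaks(tsSignal(rep(1, fs * 10), fs, "PPG")),
                 "no beat")
  expect_length(out$event_times, 0)
})

test_that("respiration cycles are segmented with correct timing", {
  fs <- 32
  # symmetric 0.2 Hz sine: 12 b/min, insp = exp = 2.5 s
  s <- tsSignal(sin(2 * pi * 0.2 * (0:(fs * 60 - 1)) / fs - pi / 2), fs, "RESP")
  st <- respStats(detectRespCycles(s))
  expect_equal(st$breathing_rate, 12, tolerance = 0.02)
  expect_equal(st$mean_insp, 2.5, tolerance = 0.1)
  expect_equal(st$mean_exp, 2.5, tolerance = 0.1)

  # resonant pacing at 0.1 Hz: 6 b/min
  s6 <- tsSignal(sin(2 * pi * 0.1 * (0:(fs * 120 - 1)) / fs - pi / 2), fs, "RESP")
  expect_equal(respStats(detectRespCycles(s6))$breathing_rate, 6,
               tolerance = 0.02)

  # asymmetric cycle: rise 1.5 s, fall 3.5 s
  r <- synthResp(12, insp_frac = 0.3, fs = fs, duration = 300)
  st2 <- respStats(detectRespCycles(r$signal))
  expect_equal(st2$mean_insp, 1.5, tolerance = 0.1)
  expect_equal(st2$mean_exp, 3.5, tolerance = 0.1)

  expect_error(detectRespCycles(tsSignal(sin(2 * pi * 0.1 * (0:(fs * 12)) / fs),
                                         fs, "RESP")), "cycles")
})

test_that("breathing rate is recovered within 0.2 b/min across 4-20 b/min", {
  for (br in c(4, 7, 12, 16, 20)) {
    r <- synthResp(br, 0.4, fs = 32, duration = 180)
    st <- respStats(detectRespCycles(r$signal))
    expect_lt(abs(st$breathing_rate - br), 0.2)
  }
})

test_that("interval construction rejects artifacts per rule", {
  b <- beatSeries(c(0, 0.8, 1.6, 2.4), kind = "R_PEAK")
  iv <- beatsToIntervals(b)
  expect_equal(iv$intervals, c(800, 800, 800))
  expect_equal(iv$dropped, 0L)

  # a spurious event splits one 800 ms gap into 100 + 700: both dropped
  tt <- seq(0, 20, by = 0.8)
  tt <- sort(c(tt, 8.1))          # 8.0 -> 8.1 -> 8.8
  iv2 <- beatsToIntervals(beatSeries(tt, kind = "R_PEAK"))
  expect_equal(iv2$dropped, 2L)
  expect_true(all(abs(iv2$intervals - 800) < 1e-6))

  expect_error(beatsToIntervals(beatSeries(c(0, 0.8), "R_PEAK")), "3 beat")
  expect_error(beatSeries(c(0, 0.5, 0.4), "R_PEAK"), "increasing")
})

test_that("interval series enforce physiological bounds", {
  expect_error(intervalSeries(c(800, 100)), "200, 3000")
  expect_error(intervalSeries(c(800, 3500)), "200, 3000")
  iv <- intervalSeries(c(800, 810), times = c(1, 1.81))
  expect_equal(iv$kind, "RR")
})
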