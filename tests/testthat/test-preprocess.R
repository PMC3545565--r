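test_that("notch filter removes 60 Hz and passes the rest", {
  fs <- 512
  tt <- (0:(fs * 20 - 1)) / fs
  mid <- seq(fs * 5, fs * 15)     # interior, clear of edge transients
  s60 <- tsSignal(sin(2 * pi * 60 * tt), fs, "ECG")
  y60 <- notchFilter(s60)$samples
  expect_lt(sd(y60[mid]) / sd(s60$samples), 0.01)
  for (f in c(1, 100)) {
    s <- tsSignal(sin(2 * pi * f * tt), fs, "ECG")
    y <- notchFilter(s)$samples
    # pass-band deviation below 1 dB
    expect_lt(abs(20 * log10(sd(y[mid]) / sd(s$samples[mid]))), 1)
  }
  z <- notchFilter(tsSignal(rep(0, fs), fs, "ECG"))
  expect_equal(z$samples, rep(0, fs))
  expect_error(notchFilter(tsSignal(1:100, 100, "ECG")), "too low")
})

test_that("FIR band-pass removes DC and drift but keeps in-band tones", {
  fs <- 512
  const <- bandpassFir(tsSignal(rep(2.5, fs * 10), fs, "ECG"))
  expect_lt(max(abs(const$samples)), 1e-6)

  tt <- (0:(fs * 60 - 1)) / fs
  x <- tsSignal(sin(2 * pi * 0.05 * tt) + 0.5 * sin(2 * pi * 10 * tt), fs, "ECG")
  y <- bandpassFir(x)
  drift_db <- 10 * log10(tonePower(x$samples, 0.05, fs) /
                           tonePower(y$samples, 0.05, fs))
  tone_db <- 10 * log10(tonePower(y$samples, 10, fs) /
                          tonePower(x$samples, 10, fs))
  expect_gt(drift_db, 20)
  expect_lt(abs(tone_db), 2)
  # explicit DC removal
  expect_lt(abs(mean(y$samples)), 1e-6 * sd(x$samples))
  expect_error(bandpassFir(x, 0.5, 300), "Nyquist")
})

test_that("in-band signals are near-invariant under repeated filtering", {
  fs <- 512
  tt <- (0:(fs * 20 - 1)) / fs
  x <- tsSignal(sin(2 * pi * 10 * tt) + 0.3 * sin(2 * pi * 3 * tt), fs, "ECG")
  once <- bandpassFir(x)
  twice <- bandpassFir(once)
  expect_lt(abs(sd(twice$samples) - sd(once$samples)) / sd(once$samples), 0.01)
  n1 <- notchFilter(x); n2 <- notchFilter(n1)
  expect_lt(abs(sd(n2$samples) - sd(n1$samples)) / sd(n1$samples), 0.01)
})

test_that("3M morphology handles constants, spikes, and SE-1 identity", {
  fs <- 512
  # constant: stage 1 unchanged, baseline equals signal, output zero
  const <- tsSignal(rep(1.7, 2000), fs, "ECG")
  st <- morphFilter3M(const, return_stages = TRUE)
  expect_equal(st$stage1$samples, rep(1.7, 2000))
  expect_equal(st$baseline$samples, rep(1.7, 2000))
  expect_equal(st$signal$samples, rep(0, 2000))

  # single-sample spike on a flat baseline is flattened by B1 = 3
  sp <- rep(0.1, 1000); sp[500] <- 5.1
  y1 <- morphFilter3M(tsSignal(sp, fs, "ECG"), se_scales = c(3, 103, 155),
                      return_stages = TRUE)$stage1$samples
  expect_equal(max(abs(y1 - 0.1)), 0)

  # SE length 1 everywhere: stage 1 is the identity
  set.seed(2)
  x <- tsSignal(rnorm(1000), fs, "ECG")
  id <- morphFilter3M(x, se_scales = c(1, 1, 1), return_stages = TRUE)
  expect_identical(id$stage1$samples, x$samples)

  expect_error(morphFilter3M(tsSignal(1:10, fs, "ECG")), "longer than signal")
  expect_error(morphFilter3M(x, se_scales = c(4, 103, 155)), "odd")
})

test_that("3M removes baseline wander while preserving QRS amplitude", {
  fs <- 512
  m <- rsaModel(rr_noise_sd = 0)
  rr <- synthRr(m, 6, 60)
  dirty <- synthEcg(rr$beat_times, fs = fs,
                    noise = noiseSpec(baseline_amp = 0.5, baseline_freq = 0.3),
                    duration = 60)
  clean <- synthEcg(rr$beat_times, fs = fs, duration = 60)
  y <- morphFilter3M(dirty$signal)
  wander_before <- tonePower(dirty$signal$samples, 0.3, fs)
  wander_after <- tonePower(y$samples, 0.3, fs)
  expect_lt(wander_after / wander_before, 0.10)   # >= 90% removed
  # QRS amplitude (R peak to S trough) preserved within 10%
  qrsAmp <- function(s, beats) {
    vapply(beats, function(bt) {
      i <- round(bt * fs) + 1
      w <- s[max(1, i - 25):min(length(s), i + 25)]
      max(w) - min(w)
    }, 0)
  }
  inner <- rr$beat_times[rr$beat_times > 1 & rr$beat_times < 59]
  a0 <- qrsAmp(clean$signal$samples, inner)
  a1 <- qrsAmp(y$samples, inner)
  expect_lt(mean(abs(a1 - a0) / a0), 0.10)
  # wander itself perturbs the filtered amplitudes by only a few percent:
  # compare against the 3M output on the wander-free signal
  aref <- qrsAmp(morphFilter3M(clean$signal)$samples, inner)
  expect_lt(max(abs(a1 - aref) / aref), 0.05)
})

test_that("preprocessing is zero-phase: no lag between input and output", {
  fs <- 512
  e <- cleanEcg(70, 60, fs)
  for (chain in list(preprocessSignal(e$signal),
                     preprocessSignal(e$signal, use_3m = FALSE))) {
    x <- e$signal$samples - mean(e$signal$samples)
    y <- chain$samples - mean(chain$samples)
    cc <- ccf(x, y, lag.max = 50, plot = FALSE)
    expect_equal(cc$lag[which.max(cc$acf)], 0)
  }
})

test_that("DOM smoothing normalises to [0,1] and reduces variance", {
  fs <- 100
  const <- domSmooth(tsSignal(rep(3, 500), fs, "RESP"), 9)
  expect_equal(const$samples, rep(0.5, 500))

  ramp <- domSmooth(tsSignal(seq(0, 1, length.out = 500), fs, "RESP"), 9)
  expect_true(all(diff(ramp$samples) >= -1e-12))
  expect_equal(range(ramp$samples), c(0, 1))

  set.seed(3)
  noise <- tsSignal(rnorm(2000), fs, "RESP")
  sm <- domSmooth(noise, 9)
  expect_equal(range(sm$samples), c(0, 1), tolerance = 1e-9)
  # the smoothing core reduces variance before normalisation
  expect_lt(var(rftkit:::movingAverage(noise$samples, 9)), var(noise$samples))
  expect_error(domSmooth(noise, 8), "odd")
  expect_error(domSmooth(tsSignal(1:5, fs, "RESP"), 7), "shorter")
})
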