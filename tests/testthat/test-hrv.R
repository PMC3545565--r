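test_that("sdnn and rmssd match hand computation and brute force", {
  expect_equal(sdnn(c(800, 800, 800, 800)), 0)
  expect_equal(sdnn(c(790, 810)), sqrt((10^2 + 10^2) / 1), tolerance = 1e-9)
  expect_equal(sdnn(c(790, 810)), 14.142, tolerance = 1e-4)

  expect_equal(rmssd(c(800, 800, 800)), 0)
  expect_equal(rmssd(c(800, 810, 790)), sqrt((10^2 + 20^2) / 2), tolerance = 1e-12)
  expect_equal(rmssd(c(800, 810, 790)), 15.811, tolerance = 1e-3)
  alt <- rep(c(790, 810), 20)
  expect_equal(rmssd(alt), 20)

  # brute-force oracle on random series
  set.seed(9)
  for (i in 1:5) {
    v <- 800 + rnorm(50, 0, 40)
    expect_equal(sdnn(v), sqrt(sum((v - mean(v))^2) / (length(v) - 1)),
                 tolerance = 1e-9)
    d <- v[-1] - v[-length(v)]
    expect_equal(rmssd(v), sqrt(sum(d^2) / length(d)), tolerance = 1e-9)
  }
  expect_error(sdnn(800), "2 intervals")
  expect_error(rmssd(c(800, 810)), "3 intervals")
})

test_that("sdnn recovers the generating spread", {
  set.seed(7)
  v <- 800 + rnorm(5000, 0, 50)
  expect_gt(sdnn(v), 48)
  expect_lt(sdnn(v), 52)
})

test_that("RR spectra locate modulation frequencies", {
  m1 <- rsaModel(peak_gain = 100, rr_noise_sd = 0, resonance_freq = 6)
  rr1 <- synthRr(m1, 6, 300)                     # 0.10 Hz modulation
  sp1 <- rrPsd(rr1$intervals)
  expect_equal(sp1$freq[which.max(sp1$power)], 0.10, tolerance = 0.1)
  expect_lt(abs(sp1$freq[which.max(sp1$power)] - 0.10), 0.01)

  m2 <- rsaModel(peak_gain = 100, rr_noise_sd = 0, resonance_freq = 15,
                 curve_width = 2)
  rr2 <- synthRr(m2, 15, 300)                    # 0.25 Hz modulation
  sp2 <- rrPsd(rr2$intervals)
  f2 <- sp2$freq[which.max(sp2$power)]
  expect_gt(f2, 0.15); expect_lte(f2, 0.4)       # lands in HF

  # constant RR: essentially no variability
  bt <- cumsum(rep(0.8, 300))
  spc <- rrPsd(intervalSeries(rep(800, 300), times = bt))
  expect_lt(sum(spc$power) * (spc$freq[2] - spc$freq[1]), 1)

  expect_error(rrPsd(intervalSeries(rep(800, 50), times = cumsum(rep(0.8, 50)))),
               "2 minutes")
})

test_that("band powers integrate the right bands", {
  # white unit-density spectrum: band powers equal band widths
  fr <- seq(0, 0.5, by = 0.005)
  spec <- structure(list(freq = fr, power = rep(1, length(fr))),
                    class = "rrSpectrum")
  bp <- bandPowers(spec)
  expect_equal(bp$tp, 0.4, tolerance = 1e-9)
  expect_equal(bp$lf_abs, 0.11, tolerance = 1e-9)
  expect_equal(bp$hf_abs, 0.25, tolerance = 1e-9)
  expect_equal(bp$lf_abs / bp$hf_abs, 0.44, tolerance = 1e-9)

  # delta-like peak wholly inside LF dominates total power
  pk <- exp(-(fr - 0.1)^2 / (2 * 0.004^2))
  spec2 <- structure(list(freq = fr, power = pk), class = "rrSpectrum")
  bp2 <- bandPowers(spec2)
  expect_gt(bp2$lf_abs / bp2$tp, 0.9)

  zero <- structure(list(freq = fr, power = rep(0, length(fr))),
                    class = "rrSpectrum")
  expect_equal(unlist(bandPowers(zero)), c(tp = 0, lf_abs = 0, hf_abs = 0))

  coarse <- structure(list(freq = seq(0, 0.5, by = 0.05), power = rep(1, 11)),
                      class = "rrSpectrum")
  expect_error(bandPowers(coarse), "coarser")
})

test_that("normalized units sum to 100 and reproduce printed group ratios", {
  nu <- normalizedUnits(2, 1)
  expect_equal(nu$lf_nu, 66.67, tolerance = 1e-2)
  expect_equal(nu$hf_nu, 33.33, tolerance = 1e-2)
  expect_equal(nu$lf_hf, 2.0)

  # printed normalized pairs of the three study groups pin the definition
  pairs <- list(c(68.7, 31.3, 2.19), c(86.5, 13.5, 6.41), c(65.7, 34.3, 1.92))
  for (p in pairs) {
    nu <- normalizedUnits(p[1], p[2])
    expect_equal(nu$lf_nu + nu$hf_nu, 100, tolerance = 1e-6)
    expect_equal(nu$lf_hf, p[3], tolerance = 0.01)
  }
  # property: lf_nu + hf_nu = 100 and ratio consistency for random powers
  set.seed(4)
  for (i in 1:20) {
    lf <- runif(1, 0, 2000); hf <- runif(1, 1e-6, 2000)
    nu <- normalizedUnits(lf, hf)
    expect_equal(nu$lf_nu + nu$hf_nu, 100, tolerance = 1e-6)
    expect_equal(nu$lf_hf, nu$lf_nu / nu$hf_nu, tolerance = 1e-9)
  }
  expect_error(normalizedUnits(0, 0), "zero")
  expect_equal(normalizedUnits(1, 0)$lf_hf, Inf)
})

test_that("coherence ratio separates coherent from incoherent rhythms", {
  m <- rsaModel(peak_gain = 100, rr_noise_sd = 0)
  rr <- synthRr(m, 6, 300)
  expect_gt(coherenceRatio(rrPsd(rr$intervals)), 2)

  set.seed(12)
  bt <- cumsum(rep(0.8, 375))
  white <- intervalSeries(800 + rnorm(375, 0, 30), times = bt)
  expect_lt(coherenceRatio(rrPsd(white)), 0.5)

  const <- rrPsd(intervalSeries(rep(800, 300), times = cumsum(rep(0.8, 300))))
  expect_error(coherenceRatio(const), "zero")
})

test_that("Parseval: spectral integral matches resampled variance within 10%", {
  for (seed in 1:4) {
    m <- rsaModel(peak_gain = 80, rr_noise_sd = 20)
    rr <- synthRr(m, 6, 300, seed = seed)
    sp <- rrPsd(rr$intervals)
    expect_lt(abs(sp$parseval_ratio - 1), 0.10)
    set.seed(seed)
    wh <- intervalSeries(800 + rnorm(375, 0, 30), times = cumsum(rep(0.8, 375)))
    expect_lt(abs(rrPsd(wh)$parseval_ratio - 1), 0.10)
  }
})

test_that("slowing RSA from 0.25 to 0.10 Hz raises lf_nu and lf_hf", {
  mk <- function(breaths) {
    m <- rsaModel(peak_gain = 80, rr_noise_sd = 15, resonance_freq = breaths,
                  curve_width = 2)
    rr <- synthRr(m, breaths, 300, seed = 21)
    bp <- bandPowers(rrPsd(rr$intervals))
    normalizedUnits(bp$lf_abs, bp$hf_abs)
  }
  fast <- mk(15)    # 0.25 Hz
  slow <- mk(6)     # 0.10 Hz
  expect_gt(slow$lf_nu, fast$lf_nu)
  expect_gt(slow$lf_hf, fast$lf_hf)
})

test_that("respStats summarises cycles consistently", {
  cyc <- respCycleSeries(seq(0, 50, by = 5), seq(2.5, 47.5, by = 5))
  st <- respStats(cyc)
  expect_equal(st$breathing_rate, 12.0)
  expect_equal(60 / mean(diff(cyc$trough_times)), st$breathing_rate,
               tolerance = 1e-6)

  paced <- synthResp(6, 0.5, fs = 32, duration = 120)$truth
  expect_equal(respStats(paced)$breathing_rate, 6.0, tolerance = 1e-6)

  gen <- synthResp(12, 0.3, fs = 32, duration = 120)$truth
  st2 <- respStats(gen)
  expect_equal(st2$breathing_rate, 12, tolerance = 0.1)
  expect_equal(st2$mean_insp, 1.5, tolerance = 0.1)
  expect_equal(st2$mean_exp, 3.5, tolerance = 0.1)

  expect_error(respStats(respCycleSeries(c(0, 5), 2.5)), "2 complete")
})

test_that("the full metric panel is internally consistent", {
  m <- rsaModel(peak_gain = 60, rr_noise_sd = 25)
  rr <- synthRr(m, 6, 300, seed = 31)
  hm <- hrvMetrics(rr$intervals)
  expect_equal(hm$lf_nu + hm$hf_nu, 100, tolerance = 1e-6)
  expect_equal(hm$lf_hf, hm$lf_abs / hm$hf_abs, tolerance = 1e-9)
  expect_gte(hm$tp, hm$lf_abs + hm$hf_abs)
  expect_gt(hm$sdnn, 0); expect_gt(hm$rmssd, 0); expect_gt(hm$cr, 0)
})
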