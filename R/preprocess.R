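# Digital cleaning chain for the monitoring module: 60 Hz notch, FIR
# band-pass, multi-scale morphological (3M) filtering, DOM smoothing /
# normalisation.  All filters are zero-phase; edges are handled by
# reflection padding.

# Zero-phase application of a symmetric (linear-phase, odd-length) FIR via
# FFT convolution: reflect-pad, convolve, undo the group delay exactly.
applyFirZeroPhase <- function(x, b) {
  nb <- length(b)
  stopifnot(nb %% 2 == 1)
  d <- (nb - 1) / 2
  n <- length(x)
  if (nb >= n) stop("filter longer than signal")
  # reflection padding (no edge repeat)
  left <- x[(d + 1):2]
  right <- x[(n - 1):(n - d)]
  xp <- c(left, x, right)
  # FFT convolution at a 2-3-5-smooth length (arbitrary lengths can make the
  # mixed-radix FFT quadratic), then undo the (nb-1)/2 group delay
  np <- length(xp)
  nfft <- stats::nextn(np + nb - 1L, c(2, 3, 5))
  Y <- fft(c(xp, rep(0, nfft - np))) * fft(c(b, rep(0, nfft - nb)))
  y <- Re(fft(Y, inverse = TRUE)) / nfft
  y[(2 * d + 1):(2 * d + n)]
}

firBandpass <- function(lo, hi, fs, max_taps = 32769L) {
  trans <- min(0.5, lo)                      # Hz; narrow transition at the low edge
  order <- ceiling(3.3 * fs / trans)
  if (order %% 2 == 1) order <- order + 1
  order <- min(order, max_taps - 1L)
  signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass")
}

#' Powerline notch filter
#'
#' Second-order IIR notch (quality factor `q`) applied forward-backward, so
#' the net response is zero-phase and the stopband attenuation is doubled.
#' The digital zero sits exactly on the notch frequency.
#'
#' @param x a [tsSignal()] with `fs > 2 * freq`.
#' @param freq notch frequency in Hz (default 60, mains interference).
#' @param q quality factor; bandwidth is `freq / q` (default 30).
#' @return Filtered [tsSignal()].
#' @export
notchFilter <- function(x, freq = 60, q = 30) {
  stopifnot(inherits(x, "tsSignal"))
  if (x$fs <= 2 * freq) {
    stop(sprintf("sampling rate %g Hz too low for a %g Hz notch", x$fs, freq))
  }
  w0 <- 2 * pi * freq / x$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  # reflection padding long enough for the narrow notch transient to die out
  s <- x$samples
  n <- length(s)
  npad <- min(n - 1L, round(3 * q / freq * x$fs))
  sp <- if (npad > 1L) {
    c(2 * s[1] - s[(npad + 1):2], s, 2 * s[n] - s[(n - 1):(n - npad)])
  } else s
  y <- as.numeric(signal::filtfilt(signal::Arma(b = b, a = a), sp))
  out <- x
  out$samples <- if (npad > 1L) y[(npad + 1):(npad + n)] else y
  out
}

#' Linear-phase FIR band-pass filter
#'
#' Windowed-design (Hamming) linear-phase FIR, applied at zero phase with
#' exact group-delay compensation, with the low-edge transition no wider
#' than 0.5 Hz.  Channel-specific default bands follow the analog front-end
#' of wearable cardiorespiratory sensors: ECG 0.5-40 Hz, PPG 0.1-20 Hz,
#' respiration 0.1-10 Hz.  The output is explicitly de-meaned, removing any
#' residual DC leakage.
#'
#' @param x a [tsSignal()].
#' @param lo,hi band edges in Hz; defaults chosen by `x$kind`.
#' @return Filtered [tsSignal()].
#' @export
bandpassFir <- function(x, lo = NULL, hi = NULL) {
  stopifnot(inherits(x, "tsSignal"))
  defaults <- list(ECG = c(0.5, 40), PPG = c(0.1, 20), RESP = c(0.1, 10))
  band <- defaults[[x$kind]]
  if (is.null(lo)) lo <- band[1]
  if (is.null(hi)) hi <- band[2]
  if (hi >= x$fs / 2) {
    stop(sprintf("upper edge %g Hz is at or above Nyquist (%g Hz)", hi, x$fs / 2))
  }
  if (!(lo > 0 && lo < hi)) stop("require 0 < lo < hi")
  b <- firBandpass(lo, hi, x$fs, max_taps = max(3L, 2L * (length(x$samples) %/% 2L) - 1L))
  out <- x
  y <- applyFirZeroPhase(x$samples, b)
  out$samples <- y - mean(y)
  out
}

# flat-SE morphology; Rcpp back end, reflection padding
morphErode  <- function(x, se) .morph_erode(x, as.integer(se))
morphDilate <- function(x, se) .morph_dilate(x, as.integer(se))
morphOpen   <- function(x, se) morphDilate(morphErode(x, se), se)
morphClose  <- function(x, se) morphErode(morphDilate(x, se), se)

defaultSeScales <- function(fs) {
  oddify <- function(k) { k <- max(1L, round(k)); if (k %% 2 == 0) k + 1L else k }
  # B1 well below the QRS width so the R tip survives the opening; B2/B3
  # longer than a QRS but shorter than a beat, for baseline estimation.
  c(oddify(0.01 * fs), oddify(0.2 * fs), oddify(0.3 * fs))
}

#' Multi-scale morphological (3M) filter
#'
#' Two-stage nonlinear cleaning with flat structuring elements (SE).
#' Stage 1 (impulse suppression) averages an open-close and a close-open at
#' the smallest scale `B1`:
#' `y1 = (close(open(x, B1), B1) + open(close(x, B1), B1)) / 2`,
#' which removes positive and negative impulses narrower than `B1` while
#' leaving wider waves essentially intact.  Stage 2 (baseline correction)
#' estimates the drifting baseline as `b = close(open(y1, B2), B3)` with the
#' two larger scales and subtracts it.  Default scales are
#' `B1 = 0.01 fs`, `B2 = 0.2 fs`, `B3 = 0.3 fs` samples (rounded odd): `B1`
#' narrower than any QRS feature, `B2`/`B3` longer than a QRS complex but
#' shorter than one beat so the baseline estimate tracks drift, not beats.
#'
#' @param x a [tsSignal()] longer than the largest SE.
#' @param se_scales integer vector `c(B1, B2, B3)` of odd SE lengths in
#'   samples; defaults derived from `fs` as above.
#' @param return_stages if `TRUE`, also return the stage-1 output and the
#'   baseline estimate.
#' @return Filtered [tsSignal()]; with `return_stages = TRUE`, a list
#'   `list(signal, stage1, baseline)`.
#' @export
morphFilter3M <- function(x, se_scales = NULL, return_stages = FALSE) {
  stopifnot(inherits(x, "tsSignal"))
  if (is.null(se_scales)) se_scales <- defaultSeScales(x$fs)
  if (length(se_scales) != 3L) stop("se_scales must have length 3 (B1, B2, B3)")
  if (any(se_scales %% 2 == 0) || any(se_scales < 1)) {
    stop("structuring element lengths must be odd and >= 1")
  }
  if (max(se_scales) > length(x$samples)) {
    stop("structuring element longer than signal")
  }
  s <- x$samples
  b1 <- se_scales[1]; b2 <- se_scales[2]; b3 <- se_scales[3]
  y1 <- 0.5 * (morphClose(morphOpen(s, b1), b1) +
               morphOpen(morphClose(s, b1), b1))
  base <- morphClose(morphOpen(y1, b2), b3)
  out <- x
  out$samples <- y1 - base
  if (return_stages) {
    st <- x; st$samples <- y1
    bl <- x; bl$samples <- base
    list(signal = out, stage1 = st, baseline = bl)
  } else {
    out
  }
}

#' Differential-operation smoothing and normalisation (DOM)
#'
#' Moving-average smoothing over an odd window followed by per-epoch min-max
#' normalisation to \[0, 1\].  A constant input has no range and maps to the
#' midpoint 0.5 by convention.
#'
#' @param x a [tsSignal()].
#' @param window odd window length in samples, `>= 3` and `< length(x)`.
#' @return Smoothed, normalised [tsSignal()].
#' @export
domSmooth <- function(x, window = 9L) {
  stopifnot(inherits(x, "tsSignal"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (window >= length(x$samples)) stop("window must be shorter than the signal")
  y <- movingAverage(x$samples, window)
  rng <- range(y)
  out <- x
  out$samples <- if (rng[2] - rng[1] < .Machine$double.eps * max(1, abs(rng[2]))) {
    rep(0.5, length(y))
  } else {
    (y - rng[1]) / (rng[2] - rng[1])
  }
  out$units <- "normalized"
  out
}

# centred moving average with reflection padding
movingAverage <- function(x, window) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  xp <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[(h + 1):(h + n)]
}

#' Standard per-channel preprocessing chain
#'
#' Convenience wrapper: 60 Hz notch (when the sampling rate allows it), FIR
#' band-pass with channel defaults, and for ECG the 3M morphological stage.
#'
#' @param x a [tsSignal()].
#' @param use_3m apply the morphological stage (default `TRUE` for ECG).
#' @return Cleaned [tsSignal()].
#' @export
preprocessSignal <- function(x, use_3m = x$kind == "ECG") {
  stopifnot(inherits(x, "tsSignal"))
  if (x$fs > 120) x <- notchFilter(x)
  x <- bandpassFir(x)
  if (isTRUE(use_3m)) x <- morphFilter3M(x)
  x
}
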