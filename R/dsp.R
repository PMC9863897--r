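#' Digital Butterworth filter design
#'
#' Designs a digital Butterworth low- or high-pass filter by bilinear
#' transformation of the analog prototype, returning transfer-function
#' coefficients suitable for [filtfilt_zero_phase()].
#'
#' @param order Filter order (positive integer).
#' @param cutoff_hz Cut-off frequency in Hz (the -3 dB point).
#' @param fs Sampling frequency in Hz. Must exceed `2 * cutoff_hz`.
#' @param type `"high"` or `"low"`.
#'
#' @return A list with numerator `b` and denominator `a` coefficient vectors
#'   (both of length `order + 1`, `a[1] == 1`).
#' @export
#' @examples
#' hp <- butter_filter(3, 20, 250, "high")
#' round(hp$b, 4)
butter_filter <- function(order, cutoff_hz, fs, type = c("high", "low")) {
  type <- match.arg(type)
  stopifnot(order >= 1, cutoff_hz > 0)
  if (fs <= 2 * cutoff_hz) {
    stop("sampling rate (", fs, " Hz) must exceed twice the cutoff (",
         cutoff_hz, " Hz)", call. = FALSE)
  }
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # pre-warped analog cutoff for the bilinear transform
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)
  if (type == "low") {
    poles <- warped * p_proto
    zeros <- complex(0)
    gain <- warped^order
  } else {
    poles <- warped / p_proto
    zeros <- rep(0 + 0i, order)
    gain <- 1
  }
  # bilinear transform s -> 2*fs*(z-1)/(z+1)
  fs2 <- 2 * fs
  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  gain <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  # zeros at infinity map to z = -1
  zd <- c(zd, rep(-1 + 0i, order - length(zeros)))
  b <- Re(gain * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# monic polynomial coefficients (descending powers) from its roots
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
  coefs
}

#' Frequency response magnitude of a digital filter
#'
#' @param coef List with `b`, `a` as returned by [butter_filter()].
#' @param freq_hz Frequencies at which to evaluate, in Hz.
#' @param fs Sampling frequency in Hz.
#' @return Gain magnitudes `|H(e^{i 2 pi f / fs})|`.
#' @export
filter_gain <- function(coef, freq_hz, fs) {
  w <- 2 * pi * freq_hz / fs
  ez <- function(cf) {
    vapply(w, function(wi) sum(cf * exp(-1i * wi * (seq_along(cf) - 1))),
           complex(1))
  }
  Mod(ez(coef$b) / ez(coef$a))
}

# steady-state filter state for a unit-step input: with initial state
# zi * x[1], a constant input produces a constant output from sample one,
# so forward-backward filtering leaves no startup transient
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  A <- rbind(-a[-1], cbind(diag(nf - 2), 0))
  solve(diag(nf - 1) - t(A), b[-1] - a[-1] * b[1])
}

#' Zero-phase forward-backward filtering
#'
#' Applies the filter forwards then backwards so the net phase response is
#' zero, with odd (point-reflected) edge padding to suppress startup
#' transients. This is the zero-lag filtering conventionally used for
#' surface-EMG conditioning.
#'
#' @inheritParams filter_gain
#' @param x Numeric signal.
#' @param padlen Samples of reflected padding at each end; defaults to
#'   `3 * (max(length(b), length(a)) - 1)`, at least three times the filter
#'   order. `x` must be longer than `padlen`.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_zero_phase <- function(coef, x, padlen = NULL) {
  b <- coef$b / coef$a[1]
  a <- coef$a / coef$a[1]
  if (is.null(padlen)) padlen <- 3 * max(length(b), length(a))
  n <- length(x)
  if (n <= padlen) {
    stop("trace of length ", n, " is too short for zero-phase filtering ",
         "(needs more than the pad length of ", padlen, " samples)",
         call. = FALSE)
  }
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

next_pow2 <- function(n) {
  if (n <= 1) return(1L)
  as.integer(2^ceiling(log2(n)))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram over 50%-overlapping Hamming-windowed
#' segments, with each segment zero-padded to `nfft` points. One-sided
#' density scaling.
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency in Hz.
#' @param nfft FFT length; defaults to the next power of 2 at or above
#'   `length(x)`.
#' @param seg_len Segment length; defaults to `min(length(x), 1024)`.
#' @param overlap Fractional segment overlap in `[0, 1)`.
#' @return A tibble with columns `freq` (Hz) and `power` (density units).
#' @export
welch_psd <- function(x, fs, nfft = next_pow2(length(x)),
                      seg_len = min(length(x), 1024L), overlap = 0.5) {
  n <- length(x)
  stopifnot(n >= 2, seg_len >= 2, nfft >= seg_len, overlap >= 0, overlap < 1)
  step <- max(1L, as.integer(floor(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  win <- hamming_window(seg_len)
  scale <- 1 / (fs * sum(win^2))
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * win
    spec <- stats::fft(c(seg, rep(0, nfft - seg_len)))
    acc <- acc + Mod(spec[seq_len(nfft %/% 2 + 1)])^2
  }
  pxx <- acc * scale / length(starts)
  # one-sided: double everything except DC and (even-nfft) Nyquist
  dbl <- rep(2, length(pxx))
  dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[length(pxx)] <- 1
  tibble::tibble(freq = (seq_along(pxx) - 1) * fs / nfft, power = pxx * dbl)
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' One-sided periodogram power spectral density
#'
#' Single (unwindowed) periodogram of the full record; suited to short
#' windows where Welch averaging would leave a single segment anyway.
#'
#' @inheritParams welch_psd
#' @return A tibble with columns `freq` (Hz) and `power`.
#' @export
periodogram_psd <- function(x, fs) {
  n <- length(x)
  stopifnot(n >= 2)
  spec <- stats::fft(x)[seq_len(n %/% 2 + 1)]
  pxx <- Mod(spec)^2 / (fs * n)
  dbl <- rep(2, length(pxx))
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(pxx)] <- 1
  tibble::tibble(freq = (seq_along(pxx) - 1) * fs / n, power = pxx * dbl)
}
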