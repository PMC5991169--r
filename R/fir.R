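# FIR band-pass filtering: windowed-sinc (Hamming) design, optional
# minimum-phase conversion via the real cepstrum, FFT convolution.

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Design a linear-phase windowed-sinc band-pass kernel
#'
#' Hamming-windowed sinc design. The transition bandwidth follows the rule
#' `max(1 Hz, 25% of the lower band edge)`; the implied length (about
#' `3.3 * fs / transition`) can be capped with `max_taps`, which widens the
#' effective transition (needed when filtering short epochs).
#'
#' @param low,high band edges in Hz.
#' @param sampling_rate sampling rate in Hz.
#' @param max_taps upper bound on the kernel length (forced odd).
#' @return Numeric kernel (odd length, type-I linear phase).
#' @export
fir_design <- function(low, high, sampling_rate, max_taps = Inf) {
  check_band(low, high, sampling_rate)
  tbw <- max(1, 0.25 * low)
  n <- ceiling(3.3 * sampling_rate / tbw)
  n <- min(n, max_taps)
  if (n < 9) stop_painlep("filter length %d too short", n)
  if (n %% 2 == 0) n <- n - 1
  m <- (n - 1) / 2
  k <- (-m):m
  lp <- function(fc) 2 * fc / sampling_rate * sinc_fn(2 * fc / sampling_rate * k)
  h <- (lp(high) - lp(low)) * (0.54 + 0.46 * cos(pi * k / m))
  h
}

#' Convert a linear-phase FIR kernel to minimum phase
#'
#' Real-cepstrum (homomorphic) method: the magnitude response is preserved
#' while the impulse response energy is moved to the front, giving a causal
#' filter with small, frequency-dependent delay as used for band
#' decomposition of short epochs.
#'
#' @param h linear-phase kernel.
#' @return Minimum-phase kernel of the same length.
#' @export
minimum_phase <- function(h) {
  n <- length(h)
  nfft <- 2^ceiling(log2(8 * n))
  H <- fft(c(h, rep(0, nfft - n)))
  mag <- pmax(abs(H), 1e-12 * max(abs(H)))
  cep <- Re(fft(log(mag), inverse = TRUE)) / nfft
  fold <- cep
  fold[2:(nfft / 2)] <- 2 * cep[2:(nfft / 2)]
  fold[(nfft / 2 + 2):nfft] <- 0
  hm <- Re(fft(exp(fft(fold)), inverse = TRUE)) / nfft
  hm[seq_len(n)]
}

# FFT-based causal convolution keeping the first length(x) samples.
# x may be a vector or a matrix (columns filtered independently).
fft_convolve_causal <- function(x, h) {
  if (is.matrix(x)) {
    n <- nrow(x) + length(h) - 1
    nfft <- 2^ceiling(log2(n))
    Hf <- fft(c(h, rep(0, nfft - length(h))))
    xp <- rbind(x, matrix(0, nfft - nrow(x), ncol(x)))
    y <- Re(stats::mvfft(stats::mvfft(xp) * Hf, inverse = TRUE)) / nfft
    y[seq_len(nrow(x)), , drop = FALSE]
  } else {
    n <- length(x) + length(h) - 1
    nfft <- 2^ceiling(log2(n))
    y <- Re(fft(fft(c(h, rep(0, nfft - length(h)))) *
                  fft(c(x, rep(0, nfft - length(x)))), inverse = TRUE)) / nfft
    y[seq_len(length(x))]
  }
}

# cache of designed kernels, keyed by design parameters
.kernel_cache <- new.env(parent = emptyenv())

get_kernel <- function(low, high, sampling_rate, max_taps, phase) {
  key <- paste(low, high, sampling_rate, max_taps, phase, sep = "|")
  k <- .kernel_cache[[key]]
  if (is.null(k)) {
    k <- fir_design(low, high, sampling_rate, max_taps)
    if (phase == "minimum") k <- minimum_phase(k)
    .kernel_cache[[key]] <- k
  }
  k
}

#' Band-pass filter a signal with an FIR filter
#'
#' Windowed-sinc FIR band-pass. In `"minimum"` phase mode (used for band
#' decomposition of 2-s sub-epochs) the filter is causal with minimal delay;
#' in `"zero"` mode the linear-phase group delay is compensated, giving a
#' non-causal zero-phase filter suited to the broadband pre-filter applied
#' once to the continuous recording. Output length equals input length in
#' both modes. The kernel length is capped at `length(signal) - 1` so short
#' epochs can always be filtered (the effective transition band widens).
#'
#' @param signal numeric vector, or matrix with one signal per column.
#' @param low,high band edges in Hz; must lie inside (0, Nyquist).
#' @param sampling_rate sampling rate in Hz.
#' @param phase `"minimum"` (causal, default) or `"zero"`.
#' @param max_taps optional cap on the kernel length.
#' @return Filtered signal, same shape as the input.
#' @examples
#' x <- sin(2 * pi * 20 * seq(0, 2, by = 1e-3))
#' y <- bandpass_fir(x, 1, 30, 1000)
#' @export
bandpass_fir <- function(signal, low, high, sampling_rate,
                         phase = c("minimum", "zero"), max_taps = Inf) {
  phase <- match.arg(phase)
  len <- if (is.matrix(signal)) nrow(signal) else length(signal)
  if (len < 16) stop_painlep("signal too short to filter (%d samples)", len)
  cap <- min(max_taps, len - 1)
  h <- get_kernel(low, high, sampling_rate, cap, if (phase == "minimum") "minimum" else "linear")
  if (phase == "minimum") {
    fft_convolve_causal(signal, h)
  } else {
    # zero-phase: causal convolution with the linear-phase kernel, then
    # advance by the (n-1)/2 group delay; edges padded with zeros
    delay <- (length(h) - 1) / 2
    if (is.matrix(signal)) {
      pad <- rbind(signal, matrix(0, delay, ncol(signal)))
      y <- fft_convolve_causal(pad, h)
      y[(delay + 1):(delay + len), , drop = FALSE]
    } else {
      pad <- c(signal, rep(0, delay))
      y <- fft_convolve_causal(pad, h)
      y[(delay + 1):(delay + len)]
    }
  }
}
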