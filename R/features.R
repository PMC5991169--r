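# isEEG feature extraction: magnitude (RMS), temporal variability (nMSSD),
# and the randomized sub-epoch resampling estimator that removes the
# dependence on unequal segment lengths.

#' Root mean square magnitude of an epoch
#'
#' `sqrt(mean(s^2))` over the K samples of the epoch.
#'
#' @param s numeric vector (uV), at least 2 finite samples.
#' @return RMS (uV).
#' @examples
#' epoch_rms(rep(3, 100))  # 3
#' @export
epoch_rms <- function(s) {
  if (length(s) < 2) stop_painlep("epoch must have at least 2 samples")
  if (!all(is.finite(s))) stop_painlep("epoch contains non-finite samples")
  sqrt(mean(s^2))
}

#' Normalized mean square successive difference of an epoch
#'
#' The mean of the K-1 squared successive sample differences (MSSD), divided
#' by the squared RMS so that the measure is scale-free: nMSSD quantifies
#' moment-to-moment variability independently of magnitude. For a pure
#' sinusoid of frequency f sampled at fs it approaches
#' `2 * (1 - cos(2 * pi * f / fs))`, increasing with frequency.
#'
#' @param s numeric vector, at least 2 samples, not all zero.
#' @return dimensionless nMSSD.
#' @examples
#' epoch_nmssd(rep(c(1, -1), 50))  # 4 (up to the finite-length edge term)
#' @export
epoch_nmssd <- function(s) {
  r2 <- epoch_rms(s)^2
  if (r2 <= 0) stop_painlep("all-zero epoch: nMSSD normalization undefined")
  mssd <- sum(diff(s)^2) / (length(s) - 1)
  mssd / r2
}

# percentile of repetition-averaged feature values; values_by_segment is a
# list (over segments) of per-sub-epoch feature values
resample_percentile <- function(values_by_segment, n_repetitions = 100,
                                percentile = 50, seed = NULL) {
  if (length(values_by_segment) == 0) stop_painlep("no segments supplied")
  if (any(vapply(values_by_segment, length, 1L) == 0))
    stop_painlep("every segment must contribute at least one sub-epoch")
  run <- function() {
    # one uniform draw per segment per repetition, vectorized per segment
    draws <- vapply(values_by_segment, function(v)
      v[sample.int(length(v), n_repetitions, replace = TRUE)],
      numeric(n_repetitions))
    if (n_repetitions == 1) draws <- matrix(draws, nrow = 1)
    reps <- rowMeans(draws)
    unname(quantile(reps, probs = percentile / 100, type = 7))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Resampled isEEG feature estimate
#'
#' Repeats `n_repetitions` times: draw one sub-epoch uniformly at random
#' from each inter-stimulus segment, evaluate `feature_fn` on each drawn
#' sub-epoch, and average across segments. Returns the requested percentile
#' (linear-interpolation quantile; 50 gives the sample median) of the
#' repetition averages. This gives every segment equal influence regardless
#' of how many sub-epochs it contains.
#'
#' @param segments list over segments, each a list of sub-epoch vectors
#'   (e.g. from [segment_to_subepochs()]).
#' @param feature_fn feature function, e.g. [epoch_rms()] or [epoch_nmssd()].
#' @param n_repetitions number of random draws (default 100).
#' @param percentile percentile of the repetition averages (default 50).
#' @param seed optional seed for reproducibility.
#' @return scalar feature estimate.
#' @export
resampled_feature <- function(segments, feature_fn, n_repetitions = 100,
                              percentile = 50, seed = NULL) {
  values <- lapply(segments, function(eps) vapply(eps, feature_fn, numeric(1)))
  resample_percentile(values, n_repetitions, percentile, seed)
}

#' Full isEEG feature vector for one subject
#'
#' Runs the complete measurement path: broadband 1--30 Hz pre-filter on the
#' continuous channel, inter-stimulus segmentation, 2-s sub-epoch tiling,
#' minimum-phase causal FIR band decomposition of each sub-epoch, RMS and
#' nMSSD per sub-epoch, and the resampled percentile estimator per
#' channel x band x feature.
#'
#' @param recording an `lep_recording`.
#' @param events event table.
#' @param channels channel labels to process (default: all in the recording).
#' @param bands band definition data.frame (default [canonical_bands()]).
#' @param n_repetitions,percentile see [resampled_feature()].
#' @param seed master seed; per-channel/band draws are derived from it.
#' @param prefilter,prefilter_phase broadband pre-filter settings.
#' @param epoch_duration sub-epoch length (s).
#' @return data.frame with columns `channel`, `band`, `feature`
#'   (`"rms"`/`"nmssd"`), `value`.
#' @export
build_feature_vector <- function(recording, events,
                                 channels = recording$channel_labels,
                                 bands = canonical_bands(),
                                 n_repetitions = 100, percentile = 50,
                                 seed = NULL, prefilter = TRUE,
                                 prefilter_phase = "zero",
                                 epoch_duration = 2) {
  fs <- recording$sampling_rate
  rows <- list()
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    rec <- recording
    if (prefilter) {
      j <- match(ch, rec$channel_labels)
      if (is.na(j)) stop_painlep("channel '%s' not in recording", ch)
      rec$data[, j] <- bandpass_fir(rec$data[, j], 1, 30, fs,
                                    phase = prefilter_phase)
    }
    segs <- extract_interstim_segments(rec, events, ch)
    eps <- lapply(segs, segment_to_subepochs, sampling_rate = fs,
                  epoch_duration = epoch_duration)
    seg_sizes <- vapply(eps, length, 1L)
    # stack all sub-epochs into one matrix and FFT once; each band filter is
    # a spectral multiply + inverse transform (causal minimum phase). Pairs
    # of real epochs are packed into the real/imaginary parts of complex
    # columns, halving the number of transforms.
    mat <- do.call(cbind, lapply(eps, function(e) do.call(cbind, e)))
    K <- nrow(mat); m <- ncol(mat)
    if (m %% 2 == 1) mat <- cbind(mat, 0)
    packed <- mat[, seq(1, ncol(mat), by = 2), drop = FALSE] +
      1i * mat[, seq(2, ncol(mat), by = 2), drop = FALSE]
    klen <- K - 1
    nfft <- stats::nextn(K + klen, 2)
    packedf <- stats::mvfft(rbind(packed,
                                  matrix(0, nfft - K, ncol(packed))))
    unpack <- function(Y) {
      out <- matrix(0, K, ncol(Y) * 2)
      out[, seq(1, ncol(out), by = 2)] <- Re(Y[seq_len(K), , drop = FALSE])
      out[, seq(2, ncol(out), by = 2)] <- Im(Y[seq_len(K), , drop = FALSE])
      out[, seq_len(m), drop = FALSE]
    }
    for (bi in seq_len(nrow(bands))) {
      h <- get_kernel(bands$low[bi], bands$high[bi], fs, klen, "minimum")
      Hf <- fft(c(h, rep(0, nfft - length(h))))
      bmat <- unpack(stats::mvfft(packedf * Hf, inverse = TRUE) / nfft)
      rms_v <- sqrt(colMeans(bmat^2))
      nms_v <- colMeans(diff(bmat)^2) / rms_v^2   # colMeans over K-1 diffs = MSSD
      split_seg <- function(v) split(v, rep(seq_along(seg_sizes), seg_sizes))
      for (feat in c("rms", "nmssd")) {
        v <- if (feat == "rms") rms_v else nms_v
        fseed <- if (is.null(seed)) NULL else
          derive_seed(seed, ci * 1000L + bi * 10L + (feat == "nmssd"))
        rows[[length(rows) + 1L]] <- data.frame(
          channel = ch, band = bands$name[bi], feature = feat,
          value = resample_percentile(split_seg(v), n_repetitions,
                                      percentile, fseed),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
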