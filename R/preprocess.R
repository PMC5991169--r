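# Epoching and single-trial LEP quantification. Conventions: times in
# seconds, sample index = floor(t * sampling_rate) (0-based time origin),
# all windows half-open [start, end).

# sample index (1-based) of time t
t2i <- function(t, fs) floor(t * fs) + 1L

#' Extract inter-stimulus EEG segments
#'
#' One segment per consecutive pair of stimulus onsets, running from 2 s
#' after a stimulus to the onset of the next one; no segment follows the
#' final stimulus. With 10--15 s inter-stimulus intervals the segments are
#' 8--13 s long.
#'
#' @param recording an `lep_recording`.
#' @param events event table sorted by onset (column `onset_s`).
#' @param channel channel label.
#' @param post_gap seconds skipped after each stimulus (default 2).
#' @return list of segments, each a list with `signal`, `start`, `end`,
#'   `length` (s).
#' @export
extract_interstim_segments <- function(recording, events, channel,
                                       post_gap = 2) {
  onsets <- events$onset_s
  if (is.unsorted(onsets, strictly = TRUE))
    stop_painlep("event onsets must be strictly increasing")
  x <- recording_channel(recording, channel)
  fs <- recording$sampling_rate
  n <- length(onsets)
  if (n < 2) stop_painlep("need at least 2 events to form a segment")
  segs <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    start <- onsets[i] + post_gap
    end <- onsets[i + 1]
    if (end <= start)
      stop_painlep("inter-stimulus interval %d is <= %g s: empty segment", i, post_gap)
    i0 <- t2i(start, fs)
    i1 <- t2i(end, fs) - 1L           # half-open [start, end)
    segs[[i]] <- list(signal = x[i0:i1], start = start, end = end,
                      length = end - start)
  }
  segs
}

#' Tile a segment into fixed-duration sub-epochs
#'
#' Non-overlapping windows of `epoch_duration` seconds tiled from the
#' segment start; a trailing remainder shorter than the window is discarded,
#' so an 8--13 s segment yields 4--6 two-second sub-epochs.
#'
#' @param segment one element of [extract_interstim_segments()], or a plain
#'   list with `signal`.
#' @param sampling_rate Hz.
#' @param epoch_duration s (default 2).
#' @return list of numeric vectors, each `epoch_duration * sampling_rate`
#'   samples.
#' @export
segment_to_subepochs <- function(segment, sampling_rate, epoch_duration = 2) {
  x <- segment$signal
  k <- as.integer(round(epoch_duration * sampling_rate))
  n_ep <- length(x) %/% k
  if (n_ep < 1)
    stop_painlep("segment (%d samples) shorter than one %g-s sub-epoch",
                 length(x), epoch_duration)
  lapply(seq_len(n_ep), function(j) x[((j - 1) * k + 1):(j * k)])
}

#' Extract peri-stimulus LEP epochs
#'
#' One epoch per event, with the time axis zeroed at stimulus onset.
#'
#' @param recording an `lep_recording`.
#' @param events event table.
#' @param channel channel label.
#' @param window c(start, end) around the onset, seconds; must cover the
#'   0.15--0.5 s N2-P2 search window.
#' @return list of epochs, each a list with `signal`, `times` (s relative to
#'   onset), `trial_index`.
#' @export
extract_lep_epochs <- function(recording, events, channel,
                               window = c(-0.5, 1.0)) {
  if (window[1] > 0.15 || window[2] < 0.5)
    stop_painlep("epoch window [%g, %g] must cover [0.15, 0.5] s", window[1], window[2])
  x <- recording_channel(recording, channel)
  fs <- recording$sampling_rate
  lapply(seq_len(nrow(events)), function(i) {
    onset <- events$onset_s[i]
    i0 <- t2i(onset + window[1], fs)
    i1 <- t2i(onset + window[2], fs) - 1L
    if (i0 < 1 || i1 > length(x))
      stop_painlep("epoch for trial %d exceeds recording bounds", events$trial_index[i])
    k0 <- t2i(onset, fs)
    list(signal = x[i0:i1], times = (seq(i0, i1) - k0) / fs,
         trial_index = events$trial_index[i])
  })
}

#' N2-P2 peak-to-peak amplitude
#'
#' The absolute difference between the most positive and most negative
#' deflections inside the post-stimulus search window (150--500 ms by
#' default). Ties between equal extrema are broken by the earliest sample.
#'
#' @param epoch an epoch from [extract_lep_epochs()] (list with `signal` and
#'   `times`).
#' @param search_window c(start, end) seconds after onset.
#' @return non-negative amplitude (uV).
#' @examples
#' ep <- list(signal = c(0, -10, 15, 0), times = c(0.1, 0.2, 0.35, 0.6))
#' n2p2_amplitude(ep)  # 25
#' @export
n2p2_amplitude <- function(epoch, search_window = c(0.15, 0.5)) {
  sel <- epoch$times >= search_window[1] & epoch$times < search_window[2]
  if (!any(sel))
    stop_painlep("search window [%g, %g] s outside epoch", search_window[1], search_window[2])
  s <- epoch$signal[sel]
  max(s) - min(s)
}

#' Per-trial table of N2-P2 amplitudes and ratings
#'
#' Epochs every trial on the LEP channel and quantifies the N2-P2 amplitude,
#' returning the trial table consumed by [fit_lep_pain()].
#'
#' @param recording an `lep_recording`.
#' @param events event table.
#' @param channel LEP channel (default "Cz").
#' @param prefilter apply the broadband 1--30 Hz pre-filter to the
#'   continuous channel before epoching.
#' @param prefilter_phase phase mode of the pre-filter.
#' @return data.frame with `trial_index`, `onset_s`, `energy_J`, `rating`,
#'   `n2p2_uV`.
#' @export
measure_trials <- function(recording, events, channel = "Cz",
                           prefilter = TRUE,
                           prefilter_phase = c("zero", "minimum")) {
  prefilter_phase <- match.arg(prefilter_phase)
  rec <- recording
  if (prefilter) {
    j <- match(channel, rec$channel_labels)
    rec$data[, j] <- bandpass_fir(rec$data[, j], 1, 30, rec$sampling_rate,
                                  phase = prefilter_phase)
  }
  eps <- extract_lep_epochs(rec, events, channel)
  data.frame(trial_index = events$trial_index, onset_s = events$onset_s,
             energy_J = events$energy_J, rating = events$rating,
             n2p2_uV = vapply(eps, n2p2_amplitude, numeric(1)))
}
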