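# Synthetic multi-subject laser-pain EEG generator.
#
# The generative model mirrors the experimental design it emulates: laser
# energies from 1 J up to a per-subject tolerable maximum (3.75-4.5 J) in
# 0.25 J steps, 10 pulses per level in pseudorandom order, inter-stimulus
# intervals uniform on 10-15 s, 1 kHz sampling. Each subject carries two
# latent isEEG traits: a background magnitude scale M_s (drives RMS) and an
# alpha-2 center frequency f_s in [11, 13] Hz (drives alpha-2 nMSSD, which
# for a narrowband process increases with its center frequency). The
# per-subject fast-pain model x = c_s * y + d_s has intercept d_s coupled
# positively to M_s and slope c_s coupled negatively to f_s.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the emulated experimental design and a cross-individual
#' coupling in which the amplitude-on-rating intercept `d` rises with
#' background magnitude (`intercept_coeffs`: d = beta0 + beta1 * M_s + noise)
#' and the slope `c` falls with alpha-2 center frequency (`slope_coeffs`:
#' c = gamma0 - gamma1 * (f_s - 12) + noise).
#'
#' @param n_subjects number of subjects in the cohort.
#' @param sampling_rate Hz.
#' @param channels channel labels; the LEP is inserted on `lep_channel`.
#' @param lep_channel channel carrying the evoked response (default "Cz").
#' @param isi_range inter-stimulus interval bounds (s), uniform distribution.
#' @param energy_min,energy_step,max_energy_range laser energy grid (J); the
#'   per-subject maximum is drawn from the grid points inside
#'   `max_energy_range`.
#' @param pulses_per_level pulses delivered at each energy level.
#' @param band_magnitude_means named per-band background RMS (uV) at M_s = 1.
#' @param intercept_coeffs c(beta0, beta1): uV and uV per unit M_s.
#' @param slope_coeffs c(gamma0, gamma1): uV/NRS and uV/NRS/Hz.
#' @param subject_noise_sds named SDs of the subject-level noise terms:
#'   `magnitude` (M_s around 1), `intercept` (uV), `slope` (uV/NRS).
#' @param trial_noise_sd SD (uV) of single-trial N2-P2 amplitude noise.
#' @param rating_noise_sd SD (NRS units) of rating noise before rounding.
#' @param feature_noise_sds named SDs (log scale) of the measurement noise on
#'   the analytic feature shortcut: `rms`, `nmssd`.
#' @param seed master seed; all randomness derives from it.
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(n_subjects = 34,
                             sampling_rate = 1000,
                             channels = "Cz",
                             lep_channel = "Cz",
                             isi_range = c(10, 15),
                             energy_min = 1.0,
                             energy_step = 0.25,
                             max_energy_range = c(3.75, 4.5),
                             pulses_per_level = 10,
                             band_magnitude_means = c(delta = 1.8, theta = 1.1,
                                                      alpha1 = 1.5, alpha2 = 1.35,
                                                      beta = 0.75),
                             intercept_coeffs = c(beta0 = -70, beta1 = 40),
                             slope_coeffs = c(gamma0 = 10, gamma1 = 3),
                             subject_noise_sds = c(magnitude = 0.25,
                                                   intercept = 4, slope = 1),
                             trial_noise_sd = 5,
                             rating_noise_sd = 1,
                             feature_noise_sds = c(rms = 0.05, nmssd = 0.03),
                             seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              sampling_rate = sampling_rate, channels = channels,
              lep_channel = lep_channel, isi_range = isi_range,
              energy_min = energy_min, energy_step = energy_step,
              max_energy_range = max_energy_range,
              pulses_per_level = as.integer(pulses_per_level),
              band_magnitude_means = band_magnitude_means,
              intercept_coeffs = unname(intercept_coeffs),
              slope_coeffs = unname(slope_coeffs),
              subject_noise_sds = subject_noise_sds,
              trial_noise_sd = trial_noise_sd,
              rating_noise_sd = rating_noise_sd,
              feature_noise_sds = feature_noise_sds,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  post_window <- 1.0  # longest post-stimulus epoch extent used downstream (s)
  if (cfg$isi_range[1] <= 2 + post_window)
    stop_painlep("isi_range lower bound (%g s) must exceed 2 s + the %g s post-stimulus window",
                 cfg$isi_range[1], post_window)
  if (cfg$sampling_rate <= 2 * 30)
    stop_painlep("sampling_rate must exceed twice the highest band edge (30 Hz)")
  maxima <- energy_grid_maxima(cfg)
  if (length(maxima) == 0)
    stop_painlep("no energy grid point falls inside max_energy_range")
  for (emax in maxima) {
    r <- (emax - cfg$energy_min) / cfg$energy_step
    if (abs(r - round(r)) > 1e-9)
      stop_painlep("energy_step must divide max_energy - energy_min (violated at %g J)", emax)
  }
  if (cfg$slope_coeffs[1] <= 0)
    stop_painlep("gamma0 must be positive: most subjects would have non-positive slope c_s")
  if (!(cfg$lep_channel %in% cfg$channels))
    stop_painlep("lep_channel '%s' is not among channels", cfg$lep_channel)
  invisible(cfg)
}

energy_grid_maxima <- function(cfg) {
  g <- seq(cfg$energy_min, cfg$max_energy_range[2] + 1e-9, by = cfg$energy_step)
  g[g >= cfg$max_energy_range[1] - 1e-9 & g <= cfg$max_energy_range[2] + 1e-9]
}

#' Draw per-subject latent profiles
#'
#' Samples, for each subject, the magnitude scale `M_s` (truncated normal
#' around 1), the alpha-2 center frequency `f_s ~ U(11, 13)` Hz, the tolerable
#' maximum energy, and the fast-pain model parameters
#' `d_s = beta0 + beta1 * M_s + noise` and
#' `c_s = gamma0 - gamma1 * (f_s - 12) + noise` truncated to `c_s > 0`.
#' Profiles whose smallest fast-pain amplitude `5 * c_s + d_s` would be
#' non-positive are redrawn so that every fast-pain trial has a positive
#' target N2-P2 amplitude.
#'
#' @param config a [generator_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return data.frame with columns `subject_id`, `M_s`, `f_s`, `c_s`, `d_s`,
#'   `max_energy`.
#' @export
draw_subject_profiles <- function(config, seed = NULL) {
  seed <- seed %||% derive_seed(config$seed, 1L)
  withr::with_seed(seed, {
    n <- config$n_subjects
    b <- config$intercept_coeffs; g <- config$slope_coeffs
    sds <- config$subject_noise_sds
    draw_one <- function(i) {
      for (try in 1:200) {
        M <- 1 + rnorm(1, 0, sds[["magnitude"]])
        if (M < 0.3) next
        f <- runif(1, 11, 13)
        d <- b[1] + b[2] * M + rnorm(1, 0, sds[["intercept"]])
        cc <- g[1] - g[2] * (f - 12) + rnorm(1, 0, sds[["slope"]])
        if (cc <= 0) next
        if (5 * cc + d <= 0) next   # smallest fast-pain amplitude must be positive
        return(c(M, f, cc, d))
      }
      stop_painlep("could not draw an admissible profile; check generator coefficients")
    }
    prof <- t(vapply(seq_len(n), draw_one, numeric(4)))
    maxima <- energy_grid_maxima(config)
    data.frame(subject_id = sprintf("S%03d", seq_len(n)),
               M_s = prof[, 1], f_s = prof[, 2],
               c_s = prof[, 3], d_s = prof[, 4],
               max_energy = maxima[sample.int(length(maxima), n, replace = TRUE)],
               stringsAsFactors = FALSE)
  })
}

#' Generate a pseudorandomized stimulus schedule
#'
#' Energy levels run from `energy_min` to the subject's maximum in
#' `energy_step` increments, each delivered `pulses_per_level` times in a
#' pseudorandom order; inter-stimulus intervals are i.i.d. uniform on
#' `isi_range`.
#'
#' @param profile one row of [draw_subject_profiles()].
#' @param config a [generator_config()].
#' @param seed optional seed.
#' @param first_onset time of the first stimulus (s).
#' @return list with `onsets` (s, strictly increasing), `energies` (J) and
#'   `level_count`.
#' @export
generate_schedule <- function(profile, config, seed = NULL, first_onset = 5) {
  levels <- seq(config$energy_min, profile$max_energy + 1e-9,
                by = config$energy_step)
  if (length(levels) < 2) stop_painlep("fewer than 2 energy levels")
  run <- function() {
    energies <- sample(rep(levels, each = config$pulses_per_level))
    n <- length(energies)
    isis <- runif(n - 1, config$isi_range[1], config$isi_range[2])
    list(onsets = first_onset + c(0, cumsum(isis)), energies = energies,
         level_count = length(levels))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Map laser energy to an NRS rating
#'
#' Affine psychometric map calibrated so that `energy_min` yields NRS 1 and
#' the subject's maximum energy yields NRS 8 (the calibration anchor of the
#' emulated design), plus Gaussian noise, rounded and clipped to 0--10.
#'
#' @param energy numeric vector of energies (J).
#' @param profile subject profile row.
#' @param config a [generator_config()].
#' @param seed optional seed.
#' @return integer ratings in 0..10.
#' @export
rating_from_energy <- function(energy, profile, config, seed = NULL) {
  run <- function() {
    raw <- 1 + 7 * (energy - config$energy_min) /
      (profile$max_energy - config$energy_min)
    noisy <- raw + rnorm(length(energy), 0, config$rating_noise_sd)
    as.integer(pmin(10, pmax(0, round(noisy))))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# normalization constant for the canonical response shape, computed once
.template_env <- new.env(parent = emptyenv())

template_shape <- function(t) {
  out <- -exp(-(t - 0.20)^2 / (2 * 0.035^2)) + exp(-(t - 0.35)^2 / (2 * 0.06^2))
  out[t < 0 | t > 0.8] <- 0
  out
}

template_norm <- function() {
  k <- .template_env$norm
  if (is.null(k)) {
    tt <- seq(0, 0.8, by = 1e-5)
    v <- template_shape(tt)
    k <- max(v) - min(v)
    .template_env$norm <- k
  }
  k
}

#' Canonical unit N2-P2 waveform
#'
#' Smooth biphasic template for the vertex laser-evoked response: a negative
#' deflection peaking near 200 ms followed by a positive deflection near
#' 350 ms, zero outside [0, 0.8] s, normalized to unit peak-to-peak
#' amplitude.
#'
#' @param times times relative to stimulus onset (s).
#' @return waveform values at `times`.
#' @examples
#' tt <- seq(-0.1, 0.9, by = 1e-3)
#' w <- lep_template(tt)
#' @export
lep_template <- function(times) {
  template_shape(times) / template_norm()
}

#' Synthesize one subject's recording and event table
#'
#' Background activity on every channel is a sum of band-limited Gaussian
#' processes whose per-band RMS is `M_s` times the configured band means; the
#' alpha-2 component is narrowband around the subject's `f_s`. At each
#' stimulus whose drawn rating exceeds 4 (fast pain), a scaled [lep_template()]
#' with discrete peak-to-peak amplitude `c_s * y + d_s +` trial noise is added
#' on the LEP channel; low-pain stimuli add no deflection.
#'
#' @param profile subject profile row.
#' @param schedule output of [generate_schedule()].
#' @param config a [generator_config()].
#' @param seed optional seed.
#' @return list with elements `recording` (class `lep_recording`) and
#'   `events` (data.frame trial_index, onset_s, energy_J, rating).
#' @export
synthesize_recording <- function(profile, schedule, config, seed = NULL) {
  run <- function() {
    fs <- config$sampling_rate
    duration <- max(schedule$onsets) + 1.5
    nsamp <- ceiling(duration * fs)
    nchan <- length(config$channels)
    bands <- canonical_bands(names(config$band_magnitude_means))
    data <- matrix(0, nsamp, nchan)
    colnames(data) <- config$channels
    # Band-limited background, accumulated in the frequency domain: one
    # independent white process per band (drawn directly as a Hermitian
    # Gaussian spectrum, so no forward transforms are needed), shaped by the
    # band kernel and scaled so the expected RMS is M_s times the configured
    # band mean (filtered unit white noise has RMS equal to the kernel's l2
    # norm). A single inverse FFT yields the background per channel.
    nfft <- stats::nextn(nsamp, 2)
    half <- nfft / 2
    white_spectrum <- function() {
      zk <- complex(real = rnorm(half - 1), imaginary = rnorm(half - 1)) *
        sqrt(nfft / 2)
      c(rnorm(1) * sqrt(nfft), zk, rnorm(1) * sqrt(nfft), Conj(rev(zk)))
    }
    for (ch in seq_len(nchan)) {
      acc <- complex(length.out = nfft)
      for (bi in seq_len(nrow(bands))) {
        target <- config$band_magnitude_means[[bands$name[bi]]] * profile$M_s
        if (target <= 0) next
        lo <- bands$low[bi]; hi <- bands$high[bi]
        if (bands$name[bi] == "alpha2") {          # narrowband trait carrier
          lo <- profile$f_s - 0.5; hi <- profile$f_s + 0.5
        }
        h <- get_kernel(lo, hi, fs, 4001, "minimum")
        scale <- target / sqrt(sum(h^2))
        Hf <- fft(c(h, rep(0, nfft - length(h))))
        acc <- acc + white_spectrum() * Hf * scale
      }
      data[, ch] <- Re(fft(acc, inverse = TRUE))[seq_len(nsamp)] / nfft
    }
    ratings <- rating_from_energy(schedule$energies, profile, config)
    lep_col <- match(config$lep_channel, config$channels)
    tt <- seq(0, 0.8, by = 1 / fs)
    w <- lep_template(tt)
    w <- w / (max(w) - min(w))                      # ptp exactly 1 on this grid
    for (i in seq_along(schedule$onsets)) {
      if (ratings[i] <= 4) next
      det <- profile$c_s * ratings[i] + profile$d_s
      x_i <- det + rnorm(1, 0, config$trial_noise_sd)
      tries <- 0
      while (x_i <= 0 && tries < 50) {
        x_i <- det + rnorm(1, 0, config$trial_noise_sd)
        tries <- tries + 1
      }
      if (x_i <= 0)
        stop_painlep("trial %d: target N2-P2 amplitude non-positive (c*y+d = %.2f uV)", i, det)
      k0 <- floor(schedule$onsets[i] * fs) + 1
      idx <- k0:(k0 + length(w) - 1)
      data[idx, lep_col] <- data[idx, lep_col] + w * x_i
    }
    rec <- new_recording(data, fs, config$channels)
    events <- data.frame(trial_index = seq_along(schedule$onsets),
                         onset_s = schedule$onsets,
                         energy_J = schedule$energies,
                         rating = ratings)
    list(recording = rec, events = events)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a full analysis-ready cohort
#'
#' Draws subject profiles and produces, per subject, a trial table and an
#' isEEG feature vector. With `waveforms = TRUE` the full signal path is run:
#' recordings are synthesized, band-pass pre-filtered, epoched, and the N2-P2
#' amplitudes and resampled isEEG features are measured from the waveforms.
#' With `waveforms = FALSE` (the fast path used for large simulation
#' studies), trial amplitudes and trait-derived feature values are drawn
#' directly from the generative model: per-band RMS is `M_s` times the band
#' mean, per-band nMSSD is the narrowband value `2(1 - cos(2 pi f_b / fs))`
#' at the band's characteristic frequency (the subject's `f_s` for alpha-2),
#' each with multiplicative log-normal measurement noise.
#'
#' @param config a [generator_config()].
#' @param waveforms run the full waveform pipeline (slow) or the analytic
#'   shortcut (fast).
#' @param n_repetitions,percentile resampling settings for the waveform path.
#' @param keep_recordings retain the raw recordings in the result
#'   (waveform path only; memory-heavy).
#' @return list of class `lep_cohort`: `profiles` plus `subjects`, a list
#'   with per-subject `subject_id`, `trials` (trial_index, onset_s, energy_J,
#'   rating, n2p2_uV) and `features` (channel, band, feature, value).
#' @export
simulate_cohort <- function(config, waveforms = FALSE,
                            n_repetitions = 100, percentile = 50,
                            keep_recordings = FALSE) {
  profiles <- draw_subject_profiles(config)
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    p <- profiles[i, ]
    sseed <- derive_seed(config$seed, 1000L + i)
    if (waveforms) {
      subjects[[i]] <- withr::with_seed(sseed, {
        sch <- generate_schedule(p, config)
        syn <- synthesize_recording(p, sch, config)
        # broadband zero-phase pre-filter applied once per channel, shared
        # by the trial measurement and the feature extraction
        for (ch in config$channels) {
          j <- match(ch, syn$recording$channel_labels)
          syn$recording$data[, j] <- bandpass_fir(
            syn$recording$data[, j], 1, 30,
            syn$recording$sampling_rate, phase = "zero")
        }
        trials <- measure_trials(syn$recording, syn$events,
                                 config$lep_channel, prefilter = FALSE)
        feats <- build_feature_vector(syn$recording, syn$events,
                                      channels = config$channels,
                                      n_repetitions = n_repetitions,
                                      percentile = percentile,
                                      seed = derive_seed(sseed, 7L),
                                      prefilter = FALSE)
        out <- list(subject_id = p$subject_id, trials = trials,
                    features = feats)
        if (keep_recordings) {
          out$recording <- syn$recording
          out$events <- syn$events
        }
        out
      })
    } else {
      subjects[[i]] <- withr::with_seed(sseed, {
        sch <- generate_schedule(p, config)
        ratings <- rating_from_energy(sch$energies, p, config)
        x <- rep(NA_real_, length(ratings))
        fast <- ratings > 4
        if (any(fast)) {
          det <- p$c_s * ratings[fast] + p$d_s
          xi <- det + rnorm(sum(fast), 0, config$trial_noise_sd)
          bad <- xi <= 0
          tries <- 0
          while (any(bad) && tries < 50) {
            xi[bad] <- det[bad] + rnorm(sum(bad), 0, config$trial_noise_sd)
            bad <- xi <= 0
            tries <- tries + 1
          }
          if (any(bad))
            stop_painlep("subject %s: non-positive fast-pain amplitude", p$subject_id)
          x[fast] <- xi
        }
        trials <- data.frame(trial_index = seq_along(sch$onsets),
                             onset_s = sch$onsets, energy_J = sch$energies,
                             rating = ratings, n2p2_uV = x)
        list(subject_id = p$subject_id, trials = trials,
             features = analytic_features(p, config))
      })
    }
  }
  structure(list(profiles = profiles, subjects = subjects, config = config),
            class = "lep_cohort")
}

# Trait-derived isEEG feature vector (fast path). Mirrors what the waveform
# pipeline measures: RMS proportional to M_s; nMSSD the narrowband value at a
# band-characteristic frequency, with the alpha-2 band carried by f_s.
analytic_features <- function(profile, config) {
  fs <- config$sampling_rate
  sds <- config$feature_noise_sds
  band_means <- config$band_magnitude_means
  band_freq <- c(delta = 2, theta = 5.5, alpha1 = 9, alpha2 = NA, beta = 18)
  band_freq[["alpha2"]] <- profile$f_s
  rows <- list()
  for (ch in config$channels) {
    rms_b <- nms_b <- numeric(0)
    for (b in names(band_means)) {
      rms_b[b] <- band_means[[b]] * profile$M_s * exp(rnorm(1, 0, sds[["rms"]]))
      nms_b[b] <- 2 * (1 - cos(2 * pi * band_freq[[b]] / fs)) *
        exp(rnorm(1, 0, sds[["nmssd"]]))
    }
    pw <- rms_b^2
    full_rms <- sqrt(sum(pw)) * exp(rnorm(1, 0, sds[["rms"]]))
    full_nms <- sum(pw * nms_b) / sum(pw) * exp(rnorm(1, 0, sds[["nmssd"]]))
    rows[[ch]] <- data.frame(
      channel = ch,
      band = rep(c("full", names(band_means)), times = 2),
      feature = rep(c("rms", "nmssd"), each = length(band_means) + 1),
      value = c(full_rms, rms_b, full_nms, nms_b),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.lep_cohort <- function(x, ...) {
  cat(sprintf("lep_cohort: %d subjects, seed %d\n",
              length(x$subjects), x$config$seed))
  invisible(x)
}
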