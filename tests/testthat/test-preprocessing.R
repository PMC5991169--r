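test_that("band-pass filter confines white noise to its passband", {
  withr::with_seed(1, {
    x <- rnorm(2e5)
    y <- bandpass_fir(x, 11, 13, 1000)
    sp <- Mod(fft(y))^2
    fr <- (seq_along(y) - 1) * 1000 / length(y)
    half <- fr <= 500
    frac <- sum(sp[half & fr >= 10 & fr <= 14]) / sum(sp[half])
    expect_gte(frac, 0.9)
  })
})

test_that("passband sinusoid and DC behave as specified", {
  t <- (0:19999) / 1000
  y <- bandpass_fir(sin(2 * pi * 20 * t), 1, 30, 1000)
  ss <- y[10001:19000]                      # discard startup transient
  expect_equal((max(ss) - min(ss)) / 2, 1, tolerance = 0.05)
  ydc <- bandpass_fir(rep(1, 10000), 1, 30, 1000)
  expect_lt(max(abs(ydc[8001:10000])), 0.01)
  expect_error(bandpass_fir(t, 0, 30, 1000), "band edges")
  expect_error(bandpass_fir(t, 1, 600, 1000), "band edges")
})

test_that("filtering is linear", {
  withr::with_seed(2, {
    s1 <- rnorm(4000); s2 <- rnorm(4000); a <- 2.7
    for (phase in c("minimum", "zero")) {
      lhs <- bandpass_fir(a * s1 + s2, 8, 10, 1000, phase = phase)
      rhs <- a * bandpass_fir(s1, 8, 10, 1000, phase = phase) +
        bandpass_fir(s2, 8, 10, 1000, phase = phase)
      expect_equal(lhs, rhs, tolerance = 1e-10)
    }
  })
})

test_that("zero-phase mode introduces no group delay", {
  x <- sinusoid(10, n = 10000)
  y <- bandpass_fir(x, 8, 12, 1000, phase = "zero")
  mid <- 3000:7000                          # away from edge effects
  expect_equal(y[mid], x[mid], tolerance = 0.02)
})

test_that("inter-stimulus segments follow the 2 s-to-next-onset rule", {
  x <- seq_len(30000) * 1.0                 # ramp encodes sample position
  rec <- signal_recording(x)
  ev <- events_at(c(0, 10, 22))
  segs <- extract_interstim_segments(rec, ev, "Cz")
  expect_length(segs, 2)                    # n events -> n - 1 segments
  expect_equal(segs[[1]]$start, 2); expect_equal(segs[[1]]$end, 10)
  expect_equal(segs[[1]]$length, 8)
  expect_equal(segs[[2]]$length, 10)
  expect_length(segs[[1]]$signal, 8000)
  expect_equal(segs[[1]]$signal[1], x[2001])  # floor(2 * 1000) + 1
  # 15 s interval gives the longest, 13 s segment
  segs2 <- extract_interstim_segments(rec, events_at(c(0, 15)), "Cz")
  expect_equal(segs2[[1]]$length, 13)
  expect_error(extract_interstim_segments(rec, events_at(c(0, 1.5)), "Cz"),
               "empty segment")
})

test_that("sub-epoch tiling discards the trailing remainder", {
  seg <- function(len_s) list(signal = numeric(len_s * 1000))
  expect_length(segment_to_subepochs(seg(8), 1000), 4)
  expect_length(segment_to_subepochs(seg(13), 1000), 6)
  expect_length(segment_to_subepochs(seg(9.5), 1000), 4)
  expect_error(segment_to_subepochs(seg(1.5), 1000), "shorter than")
  eps <- segment_to_subepochs(list(signal = seq_len(9000) * 1.0), 1000)
  expect_true(all(lengths(eps) == 2000))
  expect_equal(eps[[2]][1], 2001)           # contiguous non-overlapping tiles
})

test_that("segment bookkeeping conserves the inter-onset span", {
  cfg <- small_config()
  p <- manual_profile()
  sch <- generate_schedule(p, cfg, seed = 61)
  syn <- synthesize_recording(p, sch, cfg, seed = 62)
  segs <- extract_interstim_segments(syn$recording, syn$events, "Cz")
  span <- max(syn$events$onset_s) - min(syn$events$onset_s)
  gaps <- 2 * (nrow(syn$events) - 1)        # excluded 2-s post-stimulus windows
  expect_equal(sum(vapply(segs, `[[`, 1, "length")) + gaps, span)
})

test_that("LEP epochs are one-per-trial and onset-aligned", {
  rec <- signal_recording(rnorm(30000))
  ev <- events_at(c(5, 16, 27))
  eps <- extract_lep_epochs(rec, ev, "Cz")
  expect_length(eps, 3)
  for (ep in eps) expect_equal(min(abs(ep$times)), 0)
  expect_error(extract_lep_epochs(rec, events_at(29.9), "Cz"), "trial 1")
  expect_error(extract_lep_epochs(rec, ev, "Cz", window = c(0.2, 1)),
               "must cover")
})

test_that("epoching a clean inserted template recovers it", {
  cfg <- generator_config(
    band_magnitude_means = c(delta = 0, theta = 0, alpha1 = 0, alpha2 = 0,
                             beta = 0),
    trial_noise_sd = 0, rating_noise_sd = 0, pulses_per_level = 2)
  p <- manual_profile(c_s = 10, d_s = -30)
  sch <- generate_schedule(p, cfg, seed = 71)
  syn <- synthesize_recording(p, sch, cfg, seed = 72)
  eps <- extract_lep_epochs(syn$recording, syn$events, "Cz")
  i <- which(syn$events$rating > 4)[1]
  ep <- eps[[i]]
  x_i <- 10 * syn$events$rating[i] - 30
  w <- lep_template(ep$times)
  w <- w / (max(w) - min(w))
  expect_equal(ep$signal, w * x_i, tolerance = 1e-6)
})

test_that("N2-P2 amplitude is max minus min inside the search window", {
  times <- (0:999) / 1000
  sig <- numeric(1000)
  sig[201] <- -10; sig[351] <- 15           # spikes at 200 and 350 ms
  ep <- list(signal = sig, times = times)
  expect_equal(n2p2_amplitude(ep), 25)
  expect_equal(n2p2_amplitude(list(signal = numeric(1000), times = times)), 0)
  sig2 <- sig; sig2[101] <- -50             # 100 ms: outside window, ignored
  expect_equal(n2p2_amplitude(list(signal = sig2, times = times)), 25)
  expect_error(n2p2_amplitude(list(signal = sig, times = times + 10)),
               "outside epoch")
})

test_that("N2-P2 amplitude obeys offset invariance and positive scaling", {
  withr::with_seed(3, {
    times <- seq(-0.1, 0.9, by = 1e-3)
    for (i in 1:5) {
      sig <- rnorm(length(times))
      ep <- list(signal = sig, times = times)
      base <- n2p2_amplitude(ep)
      expect_equal(n2p2_amplitude(list(signal = sig + 17.3, times = times)),
                   base, tolerance = 1e-12)
      expect_equal(n2p2_amplitude(list(signal = 3.5 * sig, times = times)),
                   3.5 * base, tolerance = 1e-12)
      expect_gte(base, 0)
    }
  })
})
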