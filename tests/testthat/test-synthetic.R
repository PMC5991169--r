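test_that("subject profiles embed the cross-individual correlation structure", {
  cfg <- generator_config(n_subjects = 200, seed = 11)
  prof <- draw_subject_profiles(cfg)
  expect_gt(cor(prof$M_s, prof$d_s), 0)
  expect_lt(cor(prof$f_s, prof$c_s), 0)
  expect_true(all(prof$f_s >= 11 & prof$f_s <= 13))
  expect_true(all(prof$c_s > 0))
  expect_true(all(5 * prof$c_s + prof$d_s > 0))
})

test_that("noise-free profiles collapse to the deterministic coefficients", {
  cfg <- generator_config(n_subjects = 20, seed = 3,
                          intercept_coeffs = c(-30, 0),
                          slope_coeffs = c(8, 0),
                          subject_noise_sds = c(magnitude = 0, intercept = 0,
                                                slope = 0))
  prof <- draw_subject_profiles(cfg)
  expect_equal(prof$d_s, rep(-30, 20))
  expect_equal(prof$c_s, rep(8, 20))
  expect_equal(prof$M_s, rep(1, 20))
})

test_that("configuration invariants are enforced", {
  expect_error(generator_config(isi_range = c(2.5, 15)), "isi_range")
  expect_error(generator_config(sampling_rate = 50), "sampling_rate")
  expect_error(generator_config(slope_coeffs = c(-1, 3)), "gamma0")
  expect_error(generator_config(lep_channel = "Fz"), "lep_channel")
})

test_that("schedule reproduces the stated design arithmetic", {
  cfg <- generator_config(seed = 5)
  p <- manual_profile(max_energy = 3.75)
  sch <- generate_schedule(p, cfg, seed = 21)
  expect_equal(sch$level_count, 12)         # (3.75 - 1) / 0.25 + 1
  expect_length(sch$onsets, 120)            # 12 levels x 10 pulses
  gaps <- diff(sch$onsets)
  expect_true(all(gaps >= 10 & gaps <= 15))
  # each level appears exactly pulses_per_level times regardless of order
  expect_equal(sort(unique(sch$energies)), seq(1, 3.75, by = 0.25))
  expect_true(all(table(sch$energies) == 10))
  expect_error(generate_schedule(manual_profile(max_energy = 1.0), cfg),
               "fewer than 2")
})

test_that("energy-rating map honours the calibration anchors", {
  cfg <- generator_config(rating_noise_sd = 0)
  p <- manual_profile(max_energy = 4)
  grid <- seq(1, 4, by = 0.25)
  r <- rating_from_energy(grid, p, cfg)
  expect_equal(r[1], 1L)                    # energy_min -> NRS 1
  expect_equal(r[length(grid)], 8L)         # tolerable maximum -> NRS 8
  expect_true(all(diff(r) >= 0))            # monotone without noise
  cfgN <- generator_config(rating_noise_sd = 10)
  rn <- rating_from_energy(rep(grid, 20), p, cfgN, seed = 2)
  expect_true(all(rn >= 0 & rn <= 10))
  expect_true(all(rn == as.integer(rn)))
})

test_that("LEP template is a causal unit-amplitude biphasic wave", {
  tt <- seq(-0.2, 1.0, by = 1e-3)
  w <- lep_template(tt)
  expect_equal(max(w) - min(w), 1, tolerance = 1e-4)
  t_min <- tt[which.min(w)]; t_max <- tt[which.max(w)]
  expect_true(t_min >= 0.15 && t_min <= 0.5)
  expect_true(t_max >= 0.15 && t_max <= 0.5)
  expect_lt(t_min, t_max)                   # negative deflection first
  expect_true(all(w[tt < 0] == 0))
  expect_true(all(w[tt > 0.8] == 0))
})

test_that("clean synthesis reproduces the programmed amplitudes exactly", {
  cfg <- generator_config(
    band_magnitude_means = c(delta = 0, theta = 0, alpha1 = 0, alpha2 = 0,
                             beta = 0),
    trial_noise_sd = 0, rating_noise_sd = 0, pulses_per_level = 2)
  p <- manual_profile(c_s = 9, d_s = -20, max_energy = 4)
  sch <- generate_schedule(p, cfg, seed = 31)
  syn <- synthesize_recording(p, sch, cfg, seed = 32)
  expect_gte(syn$recording$duration, max(sch$onsets) + 1)
  trials <- measure_trials(syn$recording, syn$events, prefilter = FALSE)
  fast <- select_fast_pain(trials)
  expect_gt(nrow(fast), 0)
  expected <- 9 * fast$rating - 20
  expect_equal(fast$n2p2_uV, expected, tolerance = 1e-6)
  # low-pain trials carry no deflection at all
  low <- trials[trials$rating <= 4, ]
  expect_true(all(low$n2p2_uV == 0))
  # noise-free fast-pain count: levels whose mapped rating exceeds 4
  ratings_by_level <- rating_from_energy(seq(1, 4, 0.25), p, cfg)
  expect_equal(nrow(fast), sum(ratings_by_level > 4) * 2)
})

test_that("synthesis is bit-identical under a fixed seed", {
  cfg <- small_config()
  p <- manual_profile()
  sch <- generate_schedule(p, cfg, seed = 41)
  s1 <- synthesize_recording(p, sch, cfg, seed = 42)
  s2 <- synthesize_recording(p, sch, cfg, seed = 42)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$events, s2$events)
})

test_that("background magnitude scales with the subject trait M_s", {
  cfg <- small_config(trial_noise_sd = 0)
  p1 <- manual_profile(M_s = 1)
  p2 <- manual_profile(M_s = 2)
  sch <- generate_schedule(p1, cfg, seed = 51)
  s1 <- synthesize_recording(p1, sch, cfg, seed = 52)
  s2 <- synthesize_recording(p2, sch, cfg, seed = 52)
  # compare RMS over an inter-stimulus stretch (identical noise draws)
  seg1 <- extract_interstim_segments(s1$recording, s1$events, "Cz")[[1]]
  seg2 <- extract_interstim_segments(s2$recording, s2$events, "Cz")[[1]]
  a1 <- epoch_rms(bandpass_fir(seg1$signal, 11, 13, 1000))
  a2 <- epoch_rms(bandpass_fir(seg2$signal, 11, 13, 1000))
  expect_equal(a2 / a1, 2, tolerance = 0.1)
})

test_that("fast-path cohort features mirror the generator traits", {
  cfg <- small_config(n_subjects = 4, trial_noise_sd = 0.5)
  coh <- simulate_cohort(cfg, waveforms = FALSE)
  s <- coh$subjects[[1]]
  expect_equal(nrow(s$features), 12)        # 1 channel x 6 bands x 2 features
  p <- coh$profiles[1, ]
  a2 <- s$features[s$features$band == "alpha2", ]
  expect_equal(a2$value[a2$feature == "nmssd"],
               2 * (1 - cos(2 * pi * p$f_s / 1000)), tolerance = 0.15)
  expect_equal(a2$value[a2$feature == "rms"], 1.35 * p$M_s, tolerance = 0.2)
  # trial amplitudes follow the subject's line
  fast <- select_fast_pain(s$trials)
  expect_lt(max(abs(fast$n2p2_uV - (p$c_s * fast$rating + p$d_s))), 2.5)
  expect_true(all(is.na(s$trials$n2p2_uV[s$trials$rating <= 4])))
})

test_that("cohort simulation is reproducible end to end", {
  cfg <- small_config(n_subjects = 3)
  c1 <- simulate_cohort(cfg, waveforms = FALSE)
  c2 <- simulate_cohort(cfg, waveforms = FALSE)
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$subjects, c2$subjects)
})
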