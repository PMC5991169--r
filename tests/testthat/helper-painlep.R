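# Shared fixtures: small, fast configurations for module tests. Acceptance
# tests (test-acceptance.R) use the full-size stated design instead.

# shortened cohort: few pulses per level so recordings stay ~300 s
small_config <- function(n_subjects = 3, seed = 7, pulses_per_level = 2, ...) {
  generator_config(n_subjects = n_subjects, seed = seed,
                   pulses_per_level = pulses_per_level, ...)
}

# sinusoid spanning an integer number of periods when f * n / fs is integer
sinusoid <- function(f, fs = 1000, n = 2000, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * f * (0:(n - 1)) / fs + phase)
}

# build a recording directly from a signal vector
signal_recording <- function(x, fs = 1000, channel = "Cz") {
  new_recording(matrix(x, ncol = 1), fs, channel)
}

# event table from onset times
events_at <- function(onsets, energy = 2, rating = 5) {
  data.frame(trial_index = seq_along(onsets), onset_s = onsets,
             energy_J = energy, rating = rating)
}

# single-row profile for direct generator calls
manual_profile <- function(M_s = 1, f_s = 12, c_s = 10, d_s = -30,
                           max_energy = 4, subject_id = "S001") {
  data.frame(subject_id = subject_id, M_s = M_s, f_s = f_s, c_s = c_s,
             d_s = d_s, max_energy = max_energy, stringsAsFactors = FALSE)
}
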