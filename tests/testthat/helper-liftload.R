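# Shared fixtures, all generated in code.

sine_ts <- function(freq_hz, fs, dur = 2, amp = 1) {
  tt <- seq(0, dur, by = 1 / fs)
  lift_ts(amp * sin(2 * pi * freq_hz * tt), fs)
}

neutral_task <- function(load = 23) lifting_task(load, H = 25, V = 75, D = 25)

# Subject matching the hand-statics worked example: trunk 35 kg at 0.25 m,
# load at 0.45 m, arms/head negligible.
stoop_subject <- function() {
  subject(80, trunk_mass = 35, trunk_com_distance = 0.25,
          armhead_mass = 1e-9, load_lever = 0.45)
}

# A toy model with one extensor and one flexor of constant moment arms, both
# slack-free and on the force-length plateau at theta = 0.
toy_pair_model <- function(body_mass = 75) {
  ext <- mtu_group("ext", "ext_ch", "extensor", 10L,
                   mtu_params(1000, 0.2, 0.1, -1.5),
                   moment_arm_coeffs = 0.05, l_ref = 0.3)
  flx <- mtu_group("flx", "flx_ch", "flexor", 10L,
                   mtu_params(1000, 0.2, 0.1, -1.5),
                   moment_arm_coeffs = 0.05, l_ref = 0.3)
  trunk_model(subject(body_mass), groups = list(ext = ext, flx = flx))
}

# One-subject clean dataset (noiseless envelopes, fixed shape factors) for
# parameter-recovery experiments.
clean_dataset <- function(seed = 7) {
  generate_dataset(generator_config(n_subjects = 1, emg_mode = "clean",
                                    vary_shape = FALSE, seed = seed))
}

process_all <- function(ds) {
  lapply(ds$trials, function(tr) process_trial(tr, ds$subjects[[tr$subject_id]]))
}
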