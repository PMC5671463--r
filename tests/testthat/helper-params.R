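# deterministic, noise-free generator settings used across tests
noiseless_params <- function(seed = 1L, ...) {
  synth_params(noise_sd = 0, pedal_amp = 0, drift_per_min = 0,
               subject_sd = 0, power_noise_sd_w = 0, spo2_noise_sd = 0,
               delta_noise_sd = 0, seed = seed, ...)
}

cond400 <- function() rsa_condition("400m", 0.209)

# closed-form realized HHb delta for sprint k of a noiseless session
expected_hhb_delta <- function(params, profile, n_sprints, site = "muscle") {
  amps <- sprintnirs:::sprint_amplitudes(profile$amp[[site]][["hhb"]],
                                         profile$amp_trend[[site]],
                                         n_sprints, 0)
  amps * (1 - exp(-params$protocol$sprint_s / params$tau_deoxy_s))
}
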