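#' Altitude condition descriptor
#'
#' A testing condition is identified by its simulated-altitude label and the
#' inspired oxygen fraction delivered in the normobaric chamber.
#'
#' @param label Condition tag, conventionally one of `"400m"`, `"2000m"`,
#'   `"3800m"`; free text is accepted.
#' @param fio2 Inspired O2 fraction (unitless). Values above 0.209 (room air)
#'   are allowed but flagged with a warning, since the protocol only lowers
#'   oxygen.
#' @return An object of class `rsa_condition`.
#' @examples
#' rsa_condition("3800m", 0.133)
#' @export
rsa_condition <- function(label, fio2) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(fio2), length(fio2) == 1L)
  if (fio2 <= 0) stop("fio2 must be positive", call. = FALSE)
  if (fio2 > 0.209) {
    warning("fio2 = ", fio2, " exceeds room air (0.209); outside the ",
            "hypoxia range this protocol was designed for", call. = FALSE)
  }
  structure(list(label = label, fio2 = fio2), class = "rsa_condition")
}

#' Repeated-sprint protocol descriptor
#'
#' Defaults encode the standard repeated-sprint-ability test: 1 min of light
#' pedaling at 20 W, then 10-s all-out sprints separated by 20-s active
#' recoveries (1:2 work-to-rest) until task failure (cadence below 70 rpm),
#' with the ergometer in torque mode at 0.8 Nm per kg body mass.
#'
#' @param lead_in_s Duration of light pedaling before the first sprint (s).
#' @param sprint_s Sprint-phase duration (s).
#' @param recovery_s Recovery-phase duration (s).
#' @param cadence_fail_rpm Cadence threshold defining task failure (rpm).
#' @param torque_factor Torque factor (Nm per kg), metadata only.
#' @return An object of class `rsa_protocol`.
#' @export
rsa_protocol <- function(lead_in_s = 60, sprint_s = 10, recovery_s = 20,
                         cadence_fail_rpm = 70, torque_factor = 0.8) {
  if (sprint_s <= 0 || recovery_s <= 0 || lead_in_s < 0) {
    stop("protocol durations must be positive", call. = FALSE)
  }
  structure(list(lead_in_s = lead_in_s, sprint_s = sprint_s,
                 recovery_s = recovery_s, cadence_fail_rpm = cadence_fail_rpm,
                 torque_factor = torque_factor),
            class = "rsa_protocol")
}

cycle_s <- function(protocol) protocol$sprint_s + protocol$recovery_s

#' Default per-condition simulation profiles
#'
#' One profile per altitude condition, carrying the condition-dependent
#' quantities: number of sprints to exhaustion (mean and SD across
#' subject-sessions), the sprint-phase delta amplitudes per NIRS channel and
#' site, the multiplicative amplitude trend across the set, the session SpO2
#' floor, the 30-s peak oxygen uptake, the maximal heart rate, and the resting
#' pre/post femoral blood flow pair.
#'
#' Group means and spreads for sprints, SpO2, VO2 and heart rate follow the
#' published group values for this protocol; delta amplitudes and trends follow
#' the reported directions across altitude (muscle deoxygenation deltas
#' smallest and declining most at the most severe hypoxia; cerebral deltas
#' growing with hypoxia) with magnitudes typical of sprint-cycling NIRS.
#'
#' @return Named list of profiles keyed by condition label.
#' @export
default_condition_profiles <- function() {
  list(
    "400m" = list(
      fio2 = 0.209, n_sprints_mean = 29.8, n_sprints_sd = 13.7,
      amp = list(muscle   = c(o2hb = 15, hhb = 20, tsi = 20),
                 cerebral = c(o2hb = 8,  hhb = 5,  tsi = 5)),
      amp_trend = c(muscle = -0.15, cerebral = 0.25),
      spo2_end = 93.8, vo2_peak = 40.1, hr_max = 185,
      bloodflow_pre = 405, bloodflow_post = 694),
    "2000m" = list(
      fio2 = 0.165, n_sprints_mean = 19.8, n_sprints_sd = 10.2,
      amp = list(muscle   = c(o2hb = 13, hhb = 22, tsi = 18),
                 cerebral = c(o2hb = 9,  hhb = 6,  tsi = 5.5)),
      amp_trend = c(muscle = -0.2, cerebral = 0.3),
      spo2_end = 86.7, vo2_peak = 36.4, hr_max = 183,
      bloodflow_pre = 633, bloodflow_post = 847),
    "3800m" = list(
      fio2 = 0.133, n_sprints_mean = 15.4, n_sprints_sd = 9.5,
      amp = list(muscle   = c(o2hb = 11, hhb = 17, tsi = 14),
                 cerebral = c(o2hb = 10, hhb = 7,  tsi = 6)),
      amp_trend = c(muscle = -0.3, cerebral = 0.4),
      spo2_end = 76.5, vo2_peak = 32.0, hr_max = 178,
      bloodflow_pre = 631, bloodflow_post = 782)
  )
}

#' Default condition set for a three-altitude cohort
#' @return List of [rsa_condition()] objects for 400, 2000 and 3800 m.
#' @export
default_conditions <- function() {
  prof <- default_condition_profiles()
  lapply(names(prof), function(nm) rsa_condition(nm, prof[[nm]]$fio2))
}

#' Synthetic-session generator parameters
#'
#' Bundles every knob of the session generator. Channel amplitudes, the
#' number-of-sprints distribution and the saturation/metabolic endpoints are
#' condition-specific and live in `conditions` (see
#' [default_condition_profiles()]); everything else is shared.
#'
#' @param n_subjects Number of subjects in a cohort.
#' @param protocol An [rsa_protocol()].
#' @param conditions Named list of per-condition profiles.
#' @param tau_deoxy_s Mono-exponential time constant of within-sprint
#'   deoxygenation (s).
#' @param tau_reoxy_s Time constant of within-recovery reoxygenation (s).
#' @param noise_sd Additive white-noise SD per site, named vector per channel
#'   in channel units (uM for Hb channels, percentage points for TSI), or a
#'   single number recycled to all channels.
#' @param pedal_amp Pedal-stroke artifact amplitude (uM on the HHb excursion,
#'   mirrored into the other channels), present only during sprint phases.
#' @param pedal_hz Artifact frequency (Hz); default 85 rpm / 60.
#' @param drift_per_min Linear instrument drift on the concentration channels
#'   (uM per minute). TSI, being ratiometric, is generated drift-free.
#' @param subject_sd SD of the per-subject multiplicative random intercept on
#'   delta amplitude (unitless fraction).
#' @param power_best_w Best-sprint mean power (W).
#' @param power_decrement_frac Per-sprint fractional power decay.
#' @param decrement_start_sprint First sprint to which the decrement applies;
#'   sprints before it stay at `power_best_w`.
#' @param power_noise_sd_w Within-sprint white-noise SD on power (W).
#' @param delta_noise_sd Measurement-noise SD on a per-sprint delta (channel
#'   units), used by the delta-level cohort simulator
#'   [simulate_delta_cohort()].
#' @param spo2_start Session-start SpO2 (%); the per-condition floor comes from
#'   the condition profile.
#' @param spo2_noise_sd SpO2 white-noise SD (percentage points).
#' @param vo2_rest Light-pedaling oxygen uptake (ml/kg/min).
#' @param hr_rest Pre-sprint heart rate (bpm).
#' @param seed Integer seed; every draw in the generator descends from it.
#' @return An object of class `rsa_synth_params`.
#' @export
synth_params <- function(n_subjects = 11,
                         protocol = rsa_protocol(),
                         conditions = default_condition_profiles(),
                         tau_deoxy_s = 2.5,
                         tau_reoxy_s = 3,
                         noise_sd = 1,
                         pedal_amp = 1.5,
                         pedal_hz = 85 / 60,
                         drift_per_min = 0.1,
                         subject_sd = 0.15,
                         power_best_w = 750,
                         power_decrement_frac = 0.02,
                         decrement_start_sprint = 1,
                         power_noise_sd_w = 15,
                         delta_noise_sd = 1.5,
                         spo2_start = 97.5,
                         spo2_noise_sd = 0.4,
                         vo2_rest = 12,
                         hr_rest = 90,
                         seed = 1L) {
  stopifnot(inherits(protocol, "rsa_protocol"))
  if (tau_deoxy_s <= 0 || tau_reoxy_s <= 0) {
    stop("time constants must be positive", call. = FALSE)
  }
  if (subject_sd < 0 || any(unlist(noise_sd) < 0) || power_noise_sd_w < 0 ||
      spo2_noise_sd < 0 || delta_noise_sd < 0) {
    stop("all SDs must be >= 0", call. = FALSE)
  }
  if (power_decrement_frac < 0 || power_decrement_frac >= 1) {
    stop("power_decrement_frac must be in [0, 1)", call. = FALSE)
  }
  for (nm in names(conditions)) {
    amps <- unlist(conditions[[nm]]$amp)
    if (any(amps <= 0)) {
      stop("amp must be > 0 for all channels (condition ", nm, ")",
           call. = FALSE)
    }
  }
  structure(
    list(n_subjects = n_subjects, protocol = protocol,
         conditions = conditions,
         tau_deoxy_s = tau_deoxy_s, tau_reoxy_s = tau_reoxy_s,
         noise_sd = noise_sd, pedal_amp = pedal_amp, pedal_hz = pedal_hz,
         drift_per_min = drift_per_min, subject_sd = subject_sd,
         power_best_w = power_best_w,
         power_decrement_frac = power_decrement_frac,
         decrement_start_sprint = decrement_start_sprint,
         power_noise_sd_w = power_noise_sd_w,
         delta_noise_sd = delta_noise_sd,
         spo2_start = spo2_start, spo2_noise_sd = spo2_noise_sd,
         vo2_rest = vo2_rest, hr_rest = hr_rest,
         seed = as.integer(seed)),
    class = "rsa_synth_params")
}

# per-channel noise SD for a site as a named vector (o2hb, hhb, tsi)
site_noise_sd <- function(params, site) {
  ns <- params$noise_sd
  chans <- c("o2hb", "hhb", "tsi")
  if (is.list(ns)) ns <- ns[[site]]
  if (length(ns) == 1L && is.null(names(ns))) {
    return(stats::setNames(rep(ns, 3L), chans))
  }
  out <- stats::setNames(numeric(3L), chans)
  out[chans] <- ns[chans]
  if (anyNA(out)) stop("noise_sd must name channels o2hb, hhb, tsi",
                       call. = FALSE)
  out
}

# deterministic sub-seed, kept below 2^31
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(s) + 1L
}
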