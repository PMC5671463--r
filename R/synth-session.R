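# Session synthesis: piecewise mono-exponential NIRS kinetics on the
# sprint/recovery block grid, plus crank, saturation and metabolic streams.

# site-level baseline concentrations (uM) and saturation (%); fixed constants
# of the generator, not fitted to any data set
site_baselines <- function(site) {
  switch(site,
    muscle   = c(o2hb = 25, hhb = 10, tsi = 70),
    cerebral = c(o2hb = 30, hhb = 8,  tsi = 68),
    stop("unknown site ", site, call. = FALSE))
}

# evaluate a piecewise first-order response on a uniform grid.
# phases: data.frame(t0, t1, target, tau); state is continuous across phases
# and starts at `state0`. Samples use the left-closed convention [t0, t1).
piecewise_exp <- function(time_s, phases, state0 = 0) {
  out <- numeric(length(time_s))
  state <- state0
  for (p in seq_len(nrow(phases))) {
    idx <- which(time_s >= phases$t0[p] & time_s < phases$t1[p])
    if (length(idx)) {
      out[idx] <- phases$target[p] +
        (state - phases$target[p]) * exp(-(time_s[idx] - phases$t0[p]) / phases$tau[p])
    }
    state <- phases$target[p] +
      (state - phases$target[p]) *
        exp(-(phases$t1[p] - phases$t0[p]) / phases$tau[p])
  }
  # samples at or beyond the last boundary hold the final state
  idx <- which(time_s >= phases$t1[nrow(phases)])
  if (length(idx)) out[idx] <- state
  out
}

# number-of-sprints draw: rounded normal, re-drawn (with warning) below the
# floor; a deterministic request (sd = 0) below 3 is an error
draw_n_sprints <- function(mean, sd, floor = 5L, max_tries = 100L) {
  if (sd == 0) {
    n <- as.integer(round(mean))
    if (n < 1) stop("n_sprints must be >= 1", call. = FALSE)
    if (n < 3) stop("n_sprints below the protocol floor of 3", call. = FALSE)
    return(n)
  }
  floor <- max(3L, as.integer(floor))
  for (i in seq_len(max_tries)) {
    n <- as.integer(round(stats::rnorm(1, mean, sd)))
    if (n >= floor) return(n)
    warning("n_sprints draw ", n, " below floor ", floor, "; re-drawing",
            call. = FALSE)
  }
  floor
}

# true per-sprint HHb amplitude targets for one session:
# amp * (1 + subject intercept) * linear trend across the set
sprint_amplitudes <- function(amp_hhb, amp_trend, n_sprints, subject_intercept) {
  k <- seq_len(n_sprints)
  trend <- 1 + amp_trend * (k - 1) / max(1, n_sprints - 1)
  amp_hhb * (1 + subject_intercept) * trend
}

# realized closed-form deltas (max - min over the sprint window) for every
# reported channel, given the HHb amplitude targets
closed_form_deltas <- function(amps_hhb, amp, sprint_s, tau_deoxy_s) {
  frac <- 1 - exp(-sprint_s / tau_deoxy_s)
  r_o <- amp[["o2hb"]] / amp[["hhb"]]
  r_t <- amp[["tsi"]] / amp[["hhb"]]
  data.frame(
    sprint_index = rep(seq_along(amps_hhb), times = 5L),
    channel = rep(c("o2hb", "hhb", "hbdiff", "thb", "tsi"),
                  each = length(amps_hhb)),
    delta_true = c(amps_hhb * frac * r_o,
                   amps_hhb * frac,
                   amps_hhb * frac * (1 + r_o),
                   amps_hhb * frac * abs(1 - r_o),
                   amps_hhb * frac * r_t),
    stringsAsFactors = FALSE)
}

# one NIRS channel set (o2hb/hhb/tsi) for a site at its native rate
synth_nirs_site <- function(params, profile, site, rate_hz, n_sprints,
                            onsets, amps_hhb, session_end) {
  pr <- params$protocol
  time_s <- seq(0, session_end, by = 1 / rate_hz)
  amp <- profile$amp[[site]]
  r_o <- amp[["o2hb"]] / amp[["hhb"]]
  r_t <- amp[["tsi"]] / amp[["hhb"]]

  phases <- do.call(rbind, lapply(seq_len(n_sprints), function(k) {
    rbind(
      data.frame(t0 = onsets[k], t1 = onsets[k] + pr$sprint_s,
                 target = amps_hhb[k], tau = params$tau_deoxy_s),
      data.frame(t0 = onsets[k] + pr$sprint_s, t1 = onsets[k] + cycle_s(pr),
                 target = 0, tau = params$tau_reoxy_s))
  }))
  exc <- piecewise_exp(time_s, phases, state0 = 0)

  in_sprint <- rep(FALSE, length(time_s))
  for (k in seq_len(n_sprints)) {
    in_sprint <- in_sprint |
      (time_s >= onsets[k] & time_s < onsets[k] + pr$sprint_s)
  }
  # pedal-stroke artifact rides on the excursion (so it mirrors into every
  # channel); cerebral probes see a reduced amplitude
  art_amp <- params$pedal_amp * if (site == "cerebral") 0.3 else 1
  exc <- exc + art_amp * sin(2 * pi * params$pedal_hz * time_s) * in_sprint

  base <- site_baselines(site)
  drift <- params$drift_per_min * time_s / 60
  ns <- site_noise_sd(params, site)
  n <- length(time_s)
  df <- data.frame(
    time_s = time_s,
    o2hb_uM = base[["o2hb"]] - r_o * exc + drift +
      stats::rnorm(n, 0, ns[["o2hb"]]),
    hhb_uM = base[["hhb"]] + exc + drift + stats::rnorm(n, 0, ns[["hhb"]]),
    tsi_pct = base[["tsi"]] - r_t * exc + stats::rnorm(n, 0, ns[["tsi"]]))
  attr(df, "sample_rate_hz") <- rate_hz
  attr(df, "site") <- site
  attr(df, "dpf") <- if (site == "muscle") 4.0 else 6.0
  df
}

#' Generate one synthetic repeated-sprint session
#'
#' Produces a full subject-by-condition recording with the statistical
#' structure the analysis pipeline assumes: muscle (10 Hz) and cerebral
#' (50 Hz) NIRS channels driven by piecewise mono-exponential deoxygenation
#' kinetics on the sprint/recovery grid, a pedal-stroke artifact confined to
#' sprint phases, slow linear drift, crank power with a geometric per-sprint
#' decrement, cadence crossing the task-failure threshold only in the final
#' sprint, a logistic SpO2 decline sampled at 5 Hz, heart rate, and irregular
#' breath-by-breath oxygen uptake. The `truth` block records sprint onsets,
#' the per-sprint closed-form deltas for every channel, and the per-subject
#' random intercept, so detection and extraction can be scored against ground
#' truth.
#'
#' @param params An [synth_params()] object.
#' @param subject_index 1-based subject number within the cohort.
#' @param condition An [rsa_condition()]; its label must match a profile in
#'   `params$conditions`.
#' @param subject_intercept Optional pre-drawn multiplicative random intercept
#'   (used by [generate_cohort()] so a subject shares one intercept across
#'   conditions). Drawn from `N(0, subject_sd)` when `NULL`.
#' @param n_sprints Optional fixed number of sprints, bypassing the random
#'   draw.
#' @param seed Optional seed override; defaults to a sub-seed derived from
#'   `params$seed`, the subject index and the condition label.
#' @return An object of class `rsa_session`: streams (`nirs_muscle`,
#'   `nirs_cerebral`, `power`, `cadence`, `spo2`, `hr`, `vo2`), `scalars`
#'   (warm-up best power, pre/post femoral blood flow), and `truth`.
#' @examples
#' p <- synth_params(seed = 42)
#' s <- generate_session(p, 1, rsa_condition("400m", 0.209), n_sprints = 6)
#' s$truth$n_sprints
#' @export
generate_session <- function(params, subject_index, condition,
                             subject_intercept = NULL, n_sprints = NULL,
                             seed = NULL) {
  stopifnot(inherits(params, "rsa_synth_params"),
            inherits(condition, "rsa_condition"))
  profile <- params$conditions[[condition$label]]
  if (is.null(profile)) {
    stop("no condition profile named '", condition$label, "' in params",
         call. = FALSE)
  }
  pr <- params$protocol
  if (is.null(seed)) {
    seed <- derive_seed(params$seed, subject_index,
                        which(names(params$conditions) == condition$label))
  }
  set.seed(seed)

  if (is.null(subject_intercept)) {
    subject_intercept <- stats::rnorm(1, 0, params$subject_sd)
  }
  if (is.null(n_sprints)) {
    n_sprints <- draw_n_sprints(profile$n_sprints_mean, profile$n_sprints_sd)
  } else {
    n_sprints <- as.integer(n_sprints)
    if (n_sprints < 1) stop("n_sprints must be >= 1", call. = FALSE)
    if (n_sprints < 3) stop("n_sprints below the protocol floor of 3",
                            call. = FALSE)
  }

  onsets <- pr$lead_in_s + cycle_s(pr) * (seq_len(n_sprints) - 1)
  session_end <- pr$lead_in_s + cycle_s(pr) * n_sprints
  amps_hhb <- sprint_amplitudes(profile$amp$muscle[["hhb"]],
                                profile$amp_trend[["muscle"]],
                                n_sprints, subject_intercept)
  amps_hhb_cer <- sprint_amplitudes(profile$amp$cerebral[["hhb"]],
                                    profile$amp_trend[["cerebral"]],
                                    n_sprints, subject_intercept)

  nirs_muscle <- synth_nirs_site(params, profile, "muscle", 10, n_sprints,
                                 onsets, amps_hhb, session_end)
  nirs_cerebral <- synth_nirs_site(params, profile, "cerebral", 50, n_sprints,
                                   onsets, amps_hhb_cer, session_end)

  # crank streams at 10 Hz; the sprint window is closed on both ends so that
  # samples at [onset, onset + sprint_s] carry the sprint value
  t10 <- nirs_muscle$time_s
  k_dec <- pmax(0L, seq_len(n_sprints) - params$decrement_start_sprint)
  p_sprint <- params$power_best_w * (1 - params$power_decrement_frac)^k_dec
  power <- rep(20, length(t10))
  cadence <- rep(85, length(t10))
  cad_plateau <- 95 - 20 * (seq_len(n_sprints) - 1) / max(1, n_sprints - 1)
  for (k in seq_len(n_sprints)) {
    w <- t10 >= onsets[k] & t10 <= onsets[k] + pr$sprint_s
    power[w] <- p_sprint[k]
    if (k < n_sprints) {
      cadence[w] <- cad_plateau[k]
    } else {
      # task failure: cadence ramps below the threshold in the final sprint
      frac <- (t10[w] - onsets[k]) / pr$sprint_s
      cadence[w] <- cad_plateau[k] + frac * (65 - cad_plateau[k])
    }
  }
  power <- power + stats::rnorm(length(t10), 0, params$power_noise_sd_w) *
    (power > 20)
  cadence <- cadence + stats::rnorm(length(t10), 0, 1)
  power_df <- data.frame(time_s = t10, power_w = power)
  cadence_df <- data.frame(time_s = t10, cadence_rpm = cadence)

  # SpO2: logistic decline from spo2_start to the condition floor, 5 Hz
  t5 <- seq(0, session_end, by = 0.2)
  mid <- session_end / 2
  sc <- session_end / 10
  spo2 <- profile$spo2_end +
    (params$spo2_start - profile$spo2_end) / (1 + exp((t5 - mid) / sc)) +
    stats::rnorm(length(t5), 0, params$spo2_noise_sd)
  spo2_df <- data.frame(time_s = t5, spo2_pct = pmin(100, spo2))

  hr <- params$hr_rest + (profile$hr_max - params$hr_rest) *
    (1 - exp(-t5 / (session_end / 4))) + stats::rnorm(length(t5), 0, 1)
  hr_df <- data.frame(time_s = t5, hr_bpm = hr)

  # breath-by-breath VO2: intervals shorten as breathing frequency rises
  bt <- 0
  breath_t <- c()
  while (bt < session_end) {
    bf <- 20 + 40 * min(1, bt / max(1, session_end * 0.6))  # br/min
    bt <- bt + (60 / bf) * stats::runif(1, 0.85, 1.15)
    breath_t <- c(breath_t, bt)
  }
  breath_t <- breath_t[breath_t <= session_end]
  vo2 <- ifelse(breath_t < pr$lead_in_s, params$vo2_rest,
                params$vo2_rest + (profile$vo2_peak * 1.02 - params$vo2_rest) *
                  (1 - exp(-(breath_t - pr$lead_in_s) / 45))) +
    stats::rnorm(length(breath_t), 0, 1.2)
  vo2_df <- data.frame(time_s = breath_t, vo2_mlkgmin = vo2)

  warmup_best <- params$power_best_w * (1 + stats::rnorm(1, 0, 0.01))
  bf_pre <- profile$bloodflow_pre * (1 + stats::rnorm(1, 0, 0.05))
  bf_post <- profile$bloodflow_post * (1 + stats::rnorm(1, 0, 0.05))

  truth <- list(
    sprint_onsets_s = onsets,
    n_sprints = n_sprints,
    failure_sprint = n_sprints,
    subject_intercept = subject_intercept,
    sprint_mean_power_w = p_sprint,
    deltas = rbind(
      cbind(site = "muscle",
            closed_form_deltas(amps_hhb, profile$amp$muscle,
                               pr$sprint_s, params$tau_deoxy_s)),
      cbind(site = "cerebral",
            closed_form_deltas(amps_hhb_cer, profile$amp$cerebral,
                               pr$sprint_s, params$tau_deoxy_s))))

  structure(
    list(subject_id = sprintf("S%02d", subject_index),
         condition = condition, protocol = pr,
         nirs_muscle = nirs_muscle, nirs_cerebral = nirs_cerebral,
         power = power_df, cadence = cadence_df, spo2 = spo2_df, hr = hr_df,
         vo2 = vo2_df,
         scalars = list(warmup_best_w = warmup_best,
                        bloodflow_pre = bf_pre, bloodflow_post = bf_post),
         truth = truth),
    class = "rsa_session")
}

#' Generate a full cohort of synthetic sessions
#'
#' Every subject appears once per condition; the per-subject multiplicative
#' random intercept on delta amplitude is drawn once per subject and shared
#' across that subject's sessions.
#'
#' @param params An [synth_params()] object.
#' @param conditions List of [rsa_condition()] objects (default: the
#'   three-altitude study set).
#' @return List of `rsa_session` objects, one per subject x condition.
#' @export
generate_cohort <- function(params, conditions = default_conditions()) {
  stopifnot(inherits(params, "rsa_synth_params"), length(conditions) >= 1)
  set.seed(derive_seed(params$seed, 0))
  intercepts <- stats::rnorm(params$n_subjects, 0, params$subject_sd)
  sessions <- list()
  for (i in seq_len(params$n_subjects)) {
    for (cond in conditions) {
      sessions[[length(sessions) + 1L]] <-
        generate_session(params, i, cond, subject_intercept = intercepts[i])
    }
  }
  sessions
}

#' Simulate per-sprint deltas for a cohort without waveform synthesis
#'
#' Draws per-sprint deltas for one channel directly from the generator's delta
#' model -- amplitude x set-duration trend x multiplicative subject intercept,
#' plus measurement noise (`delta_noise_sd`) -- normalizes each session to the
#' five set-duration points, and returns the long table the mixed model
#' consumes. This is the generative model used for Monte-Carlo calibration of
#' the inference stage, where hundreds of cohorts are needed and the waveform
#' layer (whose extraction accuracy is validated separately) would only add
#' runtime.
#'
#' @param params An [synth_params()] object.
#' @param conditions List of [rsa_condition()] objects.
#' @param site,channel Which amplitude entry drives the deltas.
#' @param n_points Number of set-duration grid points.
#' @param seed Seed for this cohort (defaults to `params$seed`).
#' @return A long data.frame: `subject`, `condition`, `set_pct`, `delta`.
#' @export
simulate_delta_cohort <- function(params, conditions = default_conditions(),
                                  site = "muscle", channel = "hhb",
                                  n_points = 5, seed = params$seed) {
  stopifnot(inherits(params, "rsa_synth_params"))
  set.seed(seed)
  frac <- 1 - exp(-params$protocol$sprint_s / params$tau_deoxy_s)
  intercepts <- stats::rnorm(params$n_subjects, 0, params$subject_sd)
  rows <- vector("list", params$n_subjects * length(conditions))
  idx <- 1L
  for (i in seq_len(params$n_subjects)) {
    for (cond in conditions) {
      profile <- params$conditions[[cond$label]]
      if (is.null(profile)) {
        stop("no condition profile named '", cond$label, "'", call. = FALSE)
      }
      n <- draw_n_sprints(profile$n_sprints_mean, profile$n_sprints_sd,
                          floor = n_points)
      amp_ch <- profile$amp[[site]][[channel]]
      amps <- sprint_amplitudes(amp_ch, profile$amp_trend[[site]],
                                n, intercepts[i])
      deltas <- amps * frac + stats::rnorm(n, 0, params$delta_noise_sd)
      prof <- normalize_profile(deltas, n_points = n_points)
      rows[[idx]] <- data.frame(subject = sprintf("S%02d", i),
                                condition = cond$label,
                                set_pct = prof$set_pct,
                                delta = prof$delta,
                                stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  do.call(rbind, rows)
}

#' Write a session's streams and metadata to a directory
#'
#' One tab-separated file per stream
#' (`<subject>_<condition>_<stream>.tsv`) plus a JSON sidecar with the
#' protocol, condition, scalars and ground truth. UTF-8, LF line endings.
#'
#' @param session An `rsa_session`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "rsa_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, paste0(session$subject_id, "_",
                                session$condition$label, "_"))
  streams <- c("nirs_muscle", "nirs_cerebral", "power", "cadence",
               "spo2", "hr", "vo2")
  files <- character(0)
  for (s in streams) {
    f <- paste0(stem, s, ".tsv")
    utils::write.table(session[[s]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    files <- c(files, f)
  }
  meta <- list(subject_id = session$subject_id,
               condition = unclass(session$condition),
               protocol = unclass(session$protocol),
               scalars = session$scalars,
               truth = session$truth)
  f <- paste0(stem, "meta.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(files, f))
}
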