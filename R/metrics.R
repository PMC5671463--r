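# Per-session performance, saturation and metabolic summaries.

#' Mean power per sprint
#'
#' Arithmetic mean of the power samples falling in each sprint window
#' (closed interval), in segment order.
#'
#' @param time_s,power_w Crank power stream.
#' @param segments `rsa_segments` from [detect_sprints()].
#' @return Numeric vector of per-sprint mean power (W).
#' @export
per_sprint_power <- function(time_s, power_w, segments) {
  vapply(seq_len(nrow(segments)), function(s) {
    w <- time_s >= segments$t_start[s] & time_s <= segments$t_end[s]
    if (!any(w)) stop("segment ", segments$index[s],
                      " contains no power samples", call. = FALSE)
    mean(power_w[w])
  }, numeric(1))
}

#' Percent decrement score (fatigue index)
#'
#' `S_dec(%) = [1 - (S_1 + S_2 + ... + S_final) / (S_best x n)] x 100`,
#' with `S_best` the best (maximum) of the scored sprints. Zero when all
#' sprints equal the best; invariant to rescaling all powers.
#'
#' @param sprint_powers Per-sprint mean powers (W), all positive.
#' @return The percent decrement score.
#' @examples
#' fatigue_index(c(800, 700, 600))  # 12.5
#' @export
fatigue_index <- function(sprint_powers) {
  if (!length(sprint_powers)) stop("empty sprint list", call. = FALSE)
  if (any(sprint_powers <= 0)) stop("non-positive sprint power",
                                    call. = FALSE)
  (1 - sum(sprint_powers) /
     (max(sprint_powers) * length(sprint_powers))) * 100
}

# trapezoidal integral of y(t) over [t0, t1] with linear interpolation at the
# window edges; exact for piecewise-linear signals
trapz_window <- function(time_s, y, t0, t1) {
  inside <- which(time_s > t0 & time_s < t1)
  tt <- c(t0, time_s[inside], t1)
  yy <- c(stats::approx(time_s, y, xout = t0)$y,
          y[inside],
          stats::approx(time_s, y, xout = t1)$y)
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Total work over the sprint phases
#'
#' Trapezoidal integral of power over every sprint window, in kJ.
#'
#' @inheritParams per_sprint_power
#' @return Total work (kJ).
#' @export
total_work <- function(time_s, power_w, segments) {
  sum(vapply(seq_len(nrow(segments)), function(s) {
    trapz_window(time_s, power_w, segments$t_start[s], segments$t_end[s])
  }, numeric(1))) / 1000
}

#' Sprint index of task failure
#'
#' First sprint in which cadence falls below the failure threshold, or `NA`
#' if cadence never does.
#'
#' @param time_s,cadence_rpm Cadence stream.
#' @param segments `rsa_segments`.
#' @param threshold_rpm Task-failure threshold (rpm).
#' @return Integer sprint index, or `NA_integer_`.
#' @export
detect_exhaustion <- function(time_s, cadence_rpm, segments,
                              threshold_rpm = 70) {
  for (s in seq_len(nrow(segments))) {
    w <- time_s >= segments$t_start[s] & time_s <= segments$t_end[s]
    if (any(cadence_rpm[w] < threshold_rpm)) return(segments$index[s])
  }
  NA_integer_
}

#' Highest fixed-width rolling average of a time series
#'
#' Maximum over all windows `[t, t + window_s]` (every sample considered as a
#' left edge) of the time-weighted mean, computed by trapezoidal integration
#' with interpolated window edges -- appropriate for irregular breath-by-breath
#' data. Used for the highest 30-s oxygen-uptake average.
#'
#' @param time_s,x The series (span must be at least `window_s`).
#' @param window_s Window width (s).
#' @return The peak windowed mean.
#' @export
rolling_peak <- function(time_s, x, window_s = 30) {
  span <- time_s[length(time_s)] - time_s[1]
  if (span < window_s) stop("series span shorter than the window",
                            call. = FALSE)
  anchors <- time_s[time_s + window_s <= time_s[length(time_s)] + 1e-9]
  max(vapply(anchors, function(t0) {
    trapz_window(time_s, x, t0, t0 + window_s) / window_s
  }, numeric(1)))
}

#' Minimum of a raw stream
#'
#' Global minimum, used for the session pulse-oximetry (SpO2) minimum taken
#' on the raw 5 Hz stream.
#'
#' @param x Nonempty numeric stream.
#' @return The minimum value.
#' @export
stream_min <- function(x) {
  if (!length(x)) stop("empty stream", call. = FALSE)
  min(x)
}

#' Percent change from pre to post
#'
#' @param pre,post Scalar values; `pre` must be nonzero.
#' @return `(post - pre) / pre * 100`.
#' @examples
#' percent_change(400, 684)  # 71
#' @export
percent_change <- function(pre, post) {
  if (pre == 0) stop("pre must be nonzero", call. = FALSE)
  (post - pre) / pre * 100
}

#' Per-session performance summary
#'
#' Assembles the session-level summary: number of sprints, mean power (mean
#' of the per-sprint means), total work, percent decrement score, SpO2
#' minimum, highest 30-s oxygen uptake, maximal heart rate, blood-flow
#' percent change, and the pacing check (both of the first two sprints
#' reaching at least 95% of the warm-up best).
#'
#' @param session An `rsa_session`.
#' @param segments `rsa_segments` for the session.
#' @return A one-row data.frame.
#' @export
performance_summary <- function(session, segments) {
  pw <- per_sprint_power(session$power$time_s, session$power$power_w,
                         segments)
  wb <- session$scalars$warmup_best_w
  pacing_ok <- if (is.null(wb) || length(pw) < 2) NA else
    all(pw[1:2] >= 0.95 * wb)
  data.frame(
    subject = session$subject_id,
    condition = session$condition$label,
    n_sprints = nrow(segments),
    mean_power_w = mean(pw),
    total_work_kj = total_work(session$power$time_s, session$power$power_w,
                               segments),
    s_dec_pct = fatigue_index(pw),
    spo2_min_pct = stream_min(session$spo2$spo2_pct),
    vo2_peak30_mlkgmin = rolling_peak(session$vo2$time_s,
                                      session$vo2$vo2_mlkgmin, 30),
    hr_max_bpm = max(session$hr$hr_bpm),
    failure_sprint = detect_exhaustion(session$cadence$time_s,
                                       session$cadence$cadence_rpm, segments,
                                       session$protocol$cadence_fail_rpm),
    bloodflow_change_pct = if (!is.null(session$scalars$bloodflow_pre))
      percent_change(session$scalars$bloodflow_pre,
                     session$scalars$bloodflow_post) else NA_real_,
    pacing_ok = pacing_ok,
    stringsAsFactors = FALSE)
}
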