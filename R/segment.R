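# Sprint-phase segmentation referenced to the filtered muscle HHb signal,
# and per-sprint max/min/delta extraction for every channel.

# filtered derivative of a canonical sprint excursion (unit mono-exponential
# rise over sprint_s, decay over recovery), used for matched-filter onset
# refinement; returns the derivative template and the index of its onset
sprint_template <- function(protocol, rate_hz, template_tau_s,
                            cutoff_hz = 0.2, order = 4) {
  lead <- 15
  total <- lead + protocol$sprint_s + min(protocol$recovery_s, 15)
  tt <- seq(0, total, by = 1 / rate_hz)
  rise_end <- lead + protocol$sprint_s
  x <- ifelse(tt < lead, 0,
       ifelse(tt < rise_end, 1 - exp(-(tt - lead) / template_tau_s),
              (1 - exp(-protocol$sprint_s / template_tau_s)) *
                exp(-(tt - rise_end) / (template_tau_s * 1.2))))
  xf <- lowpass_zero_phase(x, rate_hz, cutoff_hz = cutoff_hz, order = order)
  d <- c(0, diff(xf)) * rate_hz
  list(deriv = d, onset_index = which.min(abs(tt - lead)))
}

# normalized cross-correlation of the derivative around one candidate with
# the template at a given shift; candidate refinement demands the full
# template window in range (an onset needs lead context), the grid fallback
# tolerates partial overlap at the series edges
template_score <- function(d, i_start, template, partial = FALSE) {
  idx <- i_start:(i_start + length(template$deriv) - 1L)
  ok <- idx >= 1L & idx <= length(d)
  if (!partial && !all(ok)) return(NA_real_)
  if (sum(ok) < length(idx) / 2) return(NA_real_)
  u <- d[idx[ok]]
  v <- template$deriv[ok]
  s <- sqrt(sum(u^2) * sum(v^2))
  if (s == 0) return(NA_real_)
  sum(u * v) / s
}

#' Detect sprint phases from the filtered muscle HHb signal
#'
#' Candidate onsets are upward crossings of the HHb first derivative over a
#' robust threshold (`k_mad` times the MAD of the derivative), separated by a
#' refractory gap `min_gap_s`. Because the zero-phase low-pass smears the
#' deoxygenation onset symmetrically in time, each candidate is then refined
#' by matched filtering: the local derivative is cross-correlated with the
#' derivative of a canonical mono-exponential sprint excursion passed through
#' the same filter, and the onset is placed at the best-scoring shift.
#' Candidates whose best correlation falls below `min_score` (signal stretches
#' that do not resemble a sprint-phase rise, e.g. edge transients) are
#' dropped. If fewer than 3 onsets survive and `grid_fallback` is set, onsets
#' fall back to the protocol grid, phase-aligned by maximizing the summed
#' template correlation over one work:rest cycle.
#'
#' Each segment spans `[onset, onset + protocol$sprint_s]`. The returned
#' count defines the number of sprints for all downstream stages.
#'
#' @param time_s,hhb Filtered muscle HHb series on a uniform grid.
#' @param protocol An [rsa_protocol()].
#' @param min_gap_s Refractory gap between onsets (s); default 25, i.e. less
#'   than one 30-s work:rest cycle.
#' @param k_mad Threshold in MAD units of the derivative.
#' @param template_tau_s Time constant of the matched-filter template (s);
#'   the expected within-sprint deoxygenation kinetics.
#' @param min_score Minimum normalized template correlation to accept a
#'   candidate.
#' @param grid_fallback Fall back to the phase-aligned protocol grid when
#'   fewer than 3 crossings are found.
#' @param refine_window_s Half-width of the shift search around each
#'   candidate (s).
#' @return A data.frame of class `rsa_segments`: `index`, `t_start`, `t_end`.
#' @export
detect_sprints <- function(time_s, hhb, protocol, min_gap_s = 25, k_mad = 3,
                           template_tau_s = 2.5, min_score = 0.5,
                           grid_fallback = TRUE, refine_window_s = 3) {
  if (length(hhb) < 10) stop("empty or too-short HHb series", call. = FALSE)
  dt <- stats::median(diff(time_s))
  rate <- 1 / dt
  d <- c(0, diff(hhb)) / dt
  thr <- k_mad * stats::mad(d)
  template <- sprint_template(protocol, rate, template_tau_s)

  onsets <- numeric(0)
  if (thr > 0) {
    cross <- which(d[-1] >= thr & d[-length(d)] < thr) + 1L
    keep <- integer(0)
    last <- -Inf
    for (i in cross) {
      if (time_s[i] - last >= min_gap_s) {
        keep <- c(keep, i)
        last <- time_s[i]
      }
    }
    w <- as.integer(round(refine_window_s / dt))
    for (i in keep) {
      shifts <- seq(-w, w)
      shifts <- shifts[i + shifts >= 1L & i + shifts <= length(d)]
      scores <- vapply(shifts, function(s) {
        template_score(d, i + s - template$onset_index + 1L, template)
      }, numeric(1))
      if (all(is.na(scores)) || max(scores, na.rm = TRUE) < min_score) next
      onsets <- c(onsets, time_s[i + shifts[which.max(scores)]])
    }
  }

  if (length(onsets) < 3) {
    if (!grid_fallback) {
      stop("fewer than 3 sprint onsets detected and grid_fallback is off",
           call. = FALSE)
    }
    onsets <- protocol_grid_onsets(time_s, d, protocol, template, dt)
  }
  segments <- data.frame(index = seq_along(onsets), t_start = onsets,
                         t_end = onsets + protocol$sprint_s)
  class(segments) <- c("rsa_segments", "data.frame")
  segments
}

# protocol-grid fallback: periodic onsets at phase + cycle * k, with the
# phase chosen to maximize the summed template correlation; a featureless
# signal (all scores equal or undefined) aligns to the protocol lead-in
protocol_grid_onsets <- function(time_s, d, protocol, template, dt) {
  cyc <- cycle_s(protocol)
  t_max <- time_s[length(time_s)]
  phases <- seq(0, cyc - dt, by = dt)
  scores <- vapply(phases, function(ph) {
    ons <- seq(ph, t_max - protocol$sprint_s, by = cyc)
    if (!length(ons)) return(NA_real_)
    s <- vapply(ons, function(o) {
      i <- which.min(abs(time_s - o))
      template_score(d, i - template$onset_index + 1L, template,
                     partial = TRUE)
    }, numeric(1))
    mean(s, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(scores)) || diff(range(scores, na.rm = TRUE)) < 1e-12) {
    ph <- protocol$lead_in_s %% cyc
  } else {
    ph <- phases[which.max(scores)]
  }
  ons <- seq(ph, t_max - protocol$sprint_s, by = cyc)
  # drop grid points before any plausible activity: keep onsets from the
  # protocol lead-in onwards when the session starts at 0
  ons[ons >= min(protocol$lead_in_s %% cyc, ph) - dt / 2]
}

#' Extract per-sprint max/min/delta for every channel
#'
#' For each segment and each channel present, the maximum and minimum are
#' taken over `[t_start, t_end + lag_s]` and the delta is their difference.
#' Both muscle and cerebral channel sets are scored against the same
#' (muscle-derived) segments, since all streams share one session clock.
#' Ties in the extrema resolve to the earliest sample.
#'
#' @param channels A channel-set data.frame from [preprocess_channels()], or
#'   a named list of them (e.g. `list(muscle = ..., cerebral = ...)`).
#' @param segments An `rsa_segments` data.frame from [detect_sprints()].
#' @param lag_s Extension of the search window into the recovery phase (s).
#' @return A long data.frame: `sprint_index`, `site`, `channel`, `t_start_s`,
#'   `max`, `min`, `delta`.
#' @export
extract_deltas <- function(channels, segments, lag_s = 0) {
  if (is.data.frame(channels)) {
    site <- attr(channels, "site")
    channels <- stats::setNames(list(channels),
                                if (is.null(site)) "site1" else site)
  }
  chan_cols <- c(o2hb = "o2hb_uM", hhb = "hhb_uM", hbdiff = "hbdiff_uM",
                 thb = "thb_uM", tsi = "tsi_pct")
  out <- list()
  for (site in names(channels)) {
    cs <- channels[[site]]
    present <- chan_cols[chan_cols %in% names(cs)]
    for (s in seq_len(nrow(segments))) {
      w <- which(cs$time_s >= segments$t_start[s] &
                 cs$time_s <= segments$t_end[s] + lag_s)
      if (!length(w)) {
        stop("segment ", segments$index[s], " outside the recorded range of ",
             site, call. = FALSE)
      }
      for (ch in names(present)) {
        v <- cs[[present[[ch]]]][w]
        out[[length(out) + 1L]] <- data.frame(
          sprint_index = segments$index[s], site = site, channel = ch,
          t_start_s = segments$t_start[s],
          max = max(v), min = min(v), delta = max(v) - min(v),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
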