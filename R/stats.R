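# Set-duration normalization and linear mixed-model inference with
# likelihood-ratio tests and Tukey-adjusted least-squares-mean contrasts.

#' Normalize per-sprint deltas to set-duration percentages
#'
#' Each participant performs a different number of sprints, so per-sprint
#' deltas are re-expressed at fixed fractions of the set (20, 40, 60, 80,
#' 100% by default). For grid point `k` of `n_points`, the target position on
#' the 1-based sprint index is `x = k * N / n_points`; integer positions take
#' the delta of that sprint, fractional positions interpolate linearly
#' between the flanking sprints. The 100% point is always the final sprint's
#' delta exactly.
#'
#' @param deltas Per-sprint delta values for one channel, in sprint order.
#' @param n_points Number of grid points; sessions with fewer sprints than
#'   grid points are rejected (the grid is undefined below `n_points`).
#' @return A data.frame with `set_pct` (percent of set) and `delta`, plus an
#'   `n_sprints_source` attribute.
#' @examples
#' normalize_profile(c(10, 8, 6, 5, 4, 3, 2))  # 20% point: 9.2
#' @export
normalize_profile <- function(deltas, n_points = 5) {
  n <- length(deltas)
  if (n == 0) stop("empty delta vector", call. = FALSE)
  if (n < n_points) {
    stop("cannot normalize ", n, " sprints to ", n_points,
         " grid points (need at least ", n_points, ")", call. = FALSE)
  }
  k <- seq_len(n_points)
  x <- k * n / n_points
  lo <- floor(x)
  w <- x - lo
  hi <- pmin(n, lo + 1)
  val <- deltas[lo] + w * (deltas[hi] - deltas[lo])
  out <- data.frame(set_pct = 100 * k / n_points, delta = val)
  attr(out, "n_sprints_source") <- n
  out
}

#' Build the long-format table for mixed-model analysis
#'
#' Normalizes each subject x condition x site x channel delta series to the
#' set-duration grid and stacks the results. The table is checked for
#' completeness (every subject must appear in every condition) and for
#' duplicate keys.
#'
#' @param deltas Long data.frame of per-sprint deltas with columns `subject`,
#'   `condition`, `sprint_index`, `site`, `channel`, `delta` (as written by
#'   the segmentation stage across a cohort).
#' @param n_points Set-duration grid size.
#' @return A long data.frame: `subject`, `condition`, `set_pct`, `site`,
#'   `channel`, `delta`, with `condition` and `set_pct` as factors.
#' @export
build_long_table <- function(deltas, n_points = 5) {
  req <- c("subject", "condition", "sprint_index", "site", "channel", "delta")
  stopifnot(all(req %in% names(deltas)))
  key <- interaction(deltas$subject, deltas$condition, deltas$sprint_index,
                     deltas$site, deltas$channel, drop = TRUE)
  if (anyDuplicated(key)) stop("duplicate (subject, condition, sprint, site,",
                               " channel) keys in delta table", call. = FALSE)
  subjects <- unique(deltas$subject)
  conditions <- unique(deltas$condition)
  for (s in subjects) {
    have <- unique(deltas$condition[deltas$subject == s])
    miss <- setdiff(conditions, have)
    if (length(miss)) {
      stop("missing session: subject ", s, ", condition ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  groups <- unique(deltas[c("subject", "condition", "site", "channel")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    d <- deltas[deltas$subject == g$subject &
                deltas$condition == g$condition &
                deltas$site == g$site & deltas$channel == g$channel, ]
    d <- d[order(d$sprint_index), ]
    prof <- normalize_profile(d$delta, n_points = n_points)
    data.frame(subject = g$subject, condition = g$condition,
               set_pct = prof$set_pct, site = g$site, channel = g$channel,
               delta = prof$delta, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$condition <- factor(out$condition, levels = sort(conditions))
  out$set_pct <- factor(out$set_pct)
  out$subject <- factor(out$subject)
  rownames(out) <- NULL
  out
}

#' Fit the repeated-measures linear mixed model for one response
#'
#' Fits `delta ~ condition + set_pct (+ condition:set_pct) + (1 | subject)`:
#' categorical fixed effects of altitude condition and set-duration point,
#' and a per-subject random intercept. The displayed fit uses REML; effect
#' p-values come from likelihood-ratio tests of maximum-likelihood refits of
#' the model with and without the effect in question, referred to a
#' chi-square with df equal to the difference in fixed-effect parameters.
#' With `interaction = TRUE` the interaction LRT compares the full against
#' the additive model, and main-effect LRTs are taken from the additive
#' model.
#'
#' @param table Long table from [build_long_table()] (or
#'   [simulate_delta_cohort()]), already restricted to one site/channel, or
#'   carrying `site`/`channel` columns filtered via the arguments below.
#' @param site,channel Optional filters applied to `table`.
#' @param interaction Include the condition x set-duration interaction.
#' @return An object of class `rsa_lmm`: the REML fit (`fit`), fixed-effect
#'   `estimates`, variance components (`varcomp`), the LRT table (`lrt`),
#'   and a `singular` flag.
#' @export
fit_mixed_model <- function(table, site = NULL, channel = NULL,
                            interaction = FALSE) {
  if (!is.null(site)) table <- table[table$site == site, ]
  if (!is.null(channel)) table <- table[table$channel == channel, ]
  if (!nrow(table)) stop("no rows to fit after filtering", call. = FALSE)
  table$condition <- droplevels(as.factor(table$condition))
  table$set_pct <- droplevels(as.factor(table$set_pct))
  table$subject <- droplevels(as.factor(table$subject))
  if (nlevels(table$condition) < 2 || nlevels(table$set_pct) < 2) {
    stop("need at least 2 levels per fixed factor", call. = FALSE)
  }
  if (nlevels(table$subject) < 2) stop("need at least 2 subjects",
                                       call. = FALSE)

  f_add <- delta ~ condition + set_pct + (1 | subject)
  f_int <- delta ~ condition * set_pct + (1 | subject)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit_display <- lme4::lmer(if (interaction) f_int else f_add, data = table,
                            REML = TRUE, control = ctrl)

  ml <- function(f) lme4::lmer(f, data = table, REML = FALSE, control = ctrl)
  m_add <- ml(f_add)
  m_nocond <- ml(delta ~ set_pct + (1 | subject))
  m_nopct <- ml(delta ~ condition + (1 | subject))
  lrt_row <- function(effect, full, reduced) {
    stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(reduced))))
    df <- attr(stats::logLik(full), "df") - attr(stats::logLik(reduced), "df")
    data.frame(effect = effect, chisq = stat, df = df,
               p = stats::pchisq(stat, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  lrt <- rbind(lrt_row("condition", m_add, m_nocond),
               lrt_row("set_pct", m_add, m_nopct))
  if (interaction) {
    lrt <- rbind(lrt, lrt_row("condition:set_pct", ml(f_int), m_add))
  }

  vc <- as.data.frame(lme4::VarCorr(fit_display))
  singular <- lme4::isSingular(fit_display)
  if (singular) {
    warning("singular mixed-model fit (random-intercept variance at the ",
            "boundary)", call. = FALSE)
  }
  structure(list(fit = fit_display,
                 estimates = lme4::fixef(fit_display),
                 varcomp = vc, lrt = lrt, singular = singular,
                 logLik_reml = as.numeric(stats::logLik(fit_display)),
                 interaction = interaction),
            class = "rsa_lmm")
}

#' @export
print.rsa_lmm <- function(x, ...) {
  cat("Linear mixed model (random intercept per subject)\n")
  cat("Fixed effects:\n")
  print(round(x$estimates, 4))
  cat("\nLikelihood-ratio tests (ML refits):\n")
  print(x$lrt, row.names = FALSE)
  if (x$singular) cat("\nNote: singular fit\n")
  invisible(x)
}

#' Tukey-adjusted pairwise contrasts of least-squares means
#'
#' All pairwise differences of least-squares (estimated marginal) means for
#' the requested fixed factor, with Tukey-method multiplicity adjustment;
#' unadjusted p-values are reported alongside. Degrees of freedom use the
#' Satterthwaite approximation.
#'
#' @param fit An `rsa_lmm` from [fit_mixed_model()], or a fitted `lmerMod`.
#' @param factor_name `"condition"` or `"set_pct"`.
#' @return A data.frame of contrasts with `estimate`, `se`, `df`, `t`,
#'   `p_adj` (Tukey) and `p_unadj`.
#' @export
pairwise_contrasts <- function(fit, factor_name = "condition") {
  model <- if (inherits(fit, "rsa_lmm")) fit$fit else fit
  lv <- nlevels(stats::model.frame(model)[[factor_name]])
  if (is.null(lv) || lv < 2) {
    stop("factor '", factor_name, "' has fewer than 2 levels", call. = FALSE)
  }
  em <- emmeans::emmeans(model, stats::as.formula(paste0("~", factor_name)),
                         lmer.df = "satterthwaite")
  adj <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
  raw <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
  data.frame(contrast = as.character(adj$contrast),
             estimate = adj$estimate, se = adj$SE, df = adj$df,
             t = adj$t.ratio, p_adj = adj$p.value, p_unadj = raw$p.value,
             stringsAsFactors = FALSE)
}
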