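test_that("normalization reproduces deltas when the grid hits whole sprints", {
  d5 <- c(3, 1, 4, 1, 5)
  expect_equal(normalize_profile(d5)$delta, d5)
  d10 <- as.numeric(1:10)
  expect_equal(normalize_profile(d10)$delta, c(2, 4, 6, 8, 10))
  expect_equal(normalize_profile(d10)$set_pct, c(20, 40, 60, 80, 100))
})

test_that("fractional positions interpolate linearly (N = 7 worked example)", {
  prof <- normalize_profile(c(10, 8, 6, 5, 4, 3, 2))
  expect_equal(prof$delta[1], 9.2)  # x = 1.4: 10 + 0.4 * (8 - 10)
  expect_equal(prof$delta[5], 2)    # 100% point is the final sprint exactly
  expect_equal(attr(prof, "n_sprints_source"), 7)
})

test_that("normalization is linear in the delta vector", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    d <- rnorm(n); e <- rnorm(n)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    expect_equal(normalize_profile(a * d + b * e)$delta,
                 a * normalize_profile(d)$delta +
                   b * normalize_profile(e)$delta,
                 tolerance = 1e-12)
  }
})

test_that("normalization rejects undefined grids", {
  expect_error(normalize_profile(numeric(0)), "empty")
  expect_error(normalize_profile(c(1, 2, 3, 4)), "at least 5")
})

make_cohort_deltas <- function(n_subj = 11, conditions = c("400m", "2000m", "3800m"),
                               n_sprints = 8) {
  do.call(rbind, lapply(seq_len(n_subj), function(i) {
    do.call(rbind, lapply(conditions, function(cc) {
      data.frame(subject = sprintf("S%02d", i), condition = cc,
                 sprint_index = seq_len(n_sprints), site = "muscle",
                 channel = "hhb", delta = rnorm(n_sprints, 15, 2),
                 stringsAsFactors = FALSE)
    }))
  }))
}

test_that("long table has one row per subject x condition x grid point", {
  set.seed(11)
  deltas <- make_cohort_deltas()
  tab <- build_long_table(deltas)
  expect_equal(nrow(tab), 11 * 3 * 5)
  expect_s3_class(tab$condition, "factor")
  expect_equal(anyDuplicated(tab[c("subject", "condition", "set_pct",
                                   "site", "channel")]), 0L)
})

test_that("long table errors on duplicates and missing sessions", {
  set.seed(12)
  deltas <- make_cohort_deltas(n_subj = 3)
  expect_error(build_long_table(rbind(deltas, deltas[1, ])), "duplicate")
  drop <- !(deltas$subject == "S02" & deltas$condition == "3800m")
  expect_error(build_long_table(deltas[drop, ]), "S02.*3800m")
})

test_that("long table round-trips through TSV losslessly", {
  set.seed(13)
  tab <- build_long_table(make_cohort_deltas(n_subj = 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.table(f, header = TRUE, sep = "\t",
                            colClasses = c(rep("character", 2), "numeric",
                                           rep("character", 2), "numeric"))
  expect_equal(back$delta, tab$delta, tolerance = 1e-12)
  expect_equal(back$subject, as.character(tab$subject))
})

test_that("mixed model recovers a known condition effect and flags structure", {
  p <- synth_params(seed = 20, subject_sd = 0.15)
  # make the highest-altitude amplitude 60% of sea level
  p$conditions[["2000m"]]$amp$muscle[["hhb"]] <-
    p$conditions[["400m"]]$amp$muscle[["hhb"]]
  p$conditions[["3800m"]]$amp$muscle[["hhb"]] <-
    0.6 * p$conditions[["400m"]]$amp$muscle[["hhb"]]
  for (cc in names(p$conditions)) {
    p$conditions[[cc]]$amp_trend[["muscle"]] <- -0.15
    p$conditions[[cc]]$n_sprints_mean <- 12
    p$conditions[[cc]]$n_sprints_sd <- 3
  }
  tab <- simulate_delta_cohort(p, seed = 77)
  fit <- fit_mixed_model(tab)
  expect_s3_class(fit, "rsa_lmm")
  expect_true(all(fit$lrt$chisq >= 0))
  expect_true(all(fit$lrt$p >= 0 & fit$lrt$p <= 1))
  expect_lt(fit$lrt$p[fit$lrt$effect == "condition"], 0.01)
  # the 3800m coefficient should be negative (lower deltas)
  expect_lt(fit$estimates[["condition3800m"]], 0)
})

test_that("degenerate random effect: near-zero intercept variance when subject_sd = 0", {
  p <- synth_params(seed = 21, subject_sd = 0, delta_noise_sd = 1.5)
  for (cc in names(p$conditions)) {
    p$conditions[[cc]]$n_sprints_mean <- 10
    p$conditions[[cc]]$n_sprints_sd <- 0
  }
  tab <- simulate_delta_cohort(p, seed = 5)
  fit <- suppressWarnings(fit_mixed_model(tab))
  vc <- fit$varcomp
  v_subj <- vc$vcov[vc$grp == "subject"]
  v_res <- vc$vcov[vc$grp == "Residual"]
  expect_lt(v_subj, 0.05 * v_res)
})

test_that("three conditions yield exactly three Tukey contrasts, adjusted >= unadjusted", {
  p <- synth_params(seed = 22)
  tab <- simulate_delta_cohort(p, seed = 9)
  fit <- fit_mixed_model(tab)
  ct <- pairwise_contrasts(fit, "condition")
  expect_equal(nrow(ct), 3)
  expect_true(all(ct$p_adj >= ct$p_unadj - 1e-12))
  ct5 <- pairwise_contrasts(fit, "set_pct")
  expect_equal(nrow(ct5), choose(5, 2))
  expect_true(all(ct5$p_adj >= ct5$p_unadj - 1e-12))
})

test_that("a two-level factor has equal adjusted and unadjusted p-values", {
  set.seed(23)
  tab <- expand.grid(subject = sprintf("S%02d", 1:8),
                     condition = c("400m", "3800m"),
                     set_pct = c(20, 40, 60, 80, 100))
  tab$delta <- rnorm(nrow(tab), 15, 2) +
    rep(rnorm(8, 0, 1.5), times = 10)
  fit <- fit_mixed_model(tab)
  ct <- pairwise_contrasts(fit, "condition")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$p_adj, ct$p_unadj, tolerance = 1e-12)
})

test_that("single-level factors and tiny designs are rejected", {
  tab <- expand.grid(subject = sprintf("S%02d", 1:6),
                     condition = "400m",
                     set_pct = c(20, 40, 60, 80, 100))
  tab$delta <- rnorm(nrow(tab))
  expect_error(fit_mixed_model(tab), "2 levels")
})

test_that("null-data LRT p-values are roughly uniform (small smoke check)", {
  p <- synth_params(seed = 30, subject_sd = 0.15, delta_noise_sd = 1.5)
  for (cc in names(p$conditions)) {
    p$conditions[[cc]]$amp$muscle[["hhb"]] <- 20
    p$conditions[[cc]]$amp_trend[["muscle"]] <- -0.15
    p$conditions[[cc]]$n_sprints_mean <- 15
    p$conditions[[cc]]$n_sprints_sd <- 5
  }
  pvals <- vapply(1:40, function(r) {
    tab <- simulate_delta_cohort(p, seed = 4000 + r)
    fit <- suppressWarnings(fit_mixed_model(tab))
    fit$lrt$p[fit$lrt$effect == "condition"]
  }, numeric(1))
  # under the null the condition LRT should not pile up near 0
  expect_gt(mean(pvals > 0.05), 0.8)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})
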