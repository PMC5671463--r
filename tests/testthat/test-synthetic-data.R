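test_that("noiseless sessions place sprint onsets on the protocol grid", {
  p <- noiseless_params()
  s <- generate_session(p, 1, cond400(), n_sprints = 10)
  expect_equal(s$truth$sprint_onsets_s, 60 + 30 * (0:9))
  expect_equal(s$truth$n_sprints, 10L)
  # streams share one clock starting at zero, strictly increasing
  for (st in c("nirs_muscle", "nirs_cerebral", "power", "spo2")) {
    expect_equal(s[[st]]$time_s[1], 0, tolerance = 1e-9,
                 info = paste(st, "starts at 0"))
  }
  for (st in c("nirs_muscle", "nirs_cerebral", "power", "spo2", "vo2")) {
    expect_true(all(diff(s[[st]]$time_s) > 0), info = st)
  }
})

test_that("noiseless per-sprint HHb max-min matches the mono-exponential closed form", {
  p <- noiseless_params()
  prof <- p$conditions[["400m"]]
  s <- generate_session(p, 1, cond400(), n_sprints = 6)
  expected <- expected_hhb_delta(p, prof, 6)
  for (k in 1:6) {
    w <- s$nirs_muscle$time_s >= s$truth$sprint_onsets_s[k] &
         s$nirs_muscle$time_s <= s$truth$sprint_onsets_s[k] + 10
    realized <- max(s$nirs_muscle$hhb_uM[w]) - min(s$nirs_muscle$hhb_uM[w])
    expect_equal(realized, expected[k], tolerance = 0.005)
  }
  # truth block records the same closed form
  tr <- s$truth$deltas
  hhb <- tr[tr$site == "muscle" & tr$channel == "hhb", ]
  expect_equal(hhb$delta_true[order(hhb$sprint_index)], expected,
               tolerance = 1e-12)
})

test_that("identical seeds give bit-identical sessions; different seeds differ", {
  p <- synth_params(seed = 7)
  s1 <- generate_session(p, 2, cond400())
  s2 <- generate_session(p, 2, cond400())
  expect_identical(s1, s2)
  s3 <- generate_session(synth_params(seed = 8), 2, cond400())
  expect_false(identical(s1$nirs_muscle$hhb_uM, s3$nirs_muscle$hhb_uM))
})

test_that("cohort has one session per subject x condition with shared intercepts", {
  p <- synth_params(n_subjects = 11, seed = 3)
  sessions <- generate_cohort(p)
  expect_length(sessions, 33)
  keys <- vapply(sessions, function(s)
    paste(s$subject_id, s$condition$label), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  ints <- vapply(sessions, function(s)
    c(s$truth$subject_intercept), numeric(1))
  subj <- vapply(sessions, function(s) s$subject_id, character(1))
  expect_true(all(tapply(ints, subj, function(x) diff(range(x))) == 0))
})

test_that("subject_sd = 0 gives identical expected amplitudes; > 0 is recovered", {
  p0 <- noiseless_params(seed = 5)
  s1 <- generate_session(p0, 1, cond400(), n_sprints = 5)
  s2 <- generate_session(p0, 9, cond400(), n_sprints = 5)
  expect_equal(s1$truth$deltas$delta_true, s2$truth$deltas$delta_true)

  # Monte-Carlo check of the multiplicative intercept: SD of per-subject mean
  # delta (relative to the noiseless expectation) recovers subject_sd
  p <- noiseless_params(seed = 11)
  p$subject_sd <- 0.2
  set.seed(21)
  rel <- replicate(200, {
    b <- rnorm(1, 0, p$subject_sd)
    s <- generate_session(p, 1, cond400(), subject_intercept = b,
                          n_sprints = 5, seed = sample.int(1e6, 1))
    tr <- s$truth$deltas
    mean(tr$delta_true[tr$site == "muscle" & tr$channel == "hhb"])
  })
  exp_mean <- mean(expected_hhb_delta(p, p$conditions[["400m"]], 5))
  expect_lt(abs(sd(rel / exp_mean) - 0.2) / 0.2, 0.15)
})

test_that("doubling amp doubles every noiseless channel excursion", {
  p1 <- noiseless_params(seed = 2)
  p2 <- noiseless_params(seed = 2)
  p2$conditions[["400m"]]$amp <- lapply(p2$conditions[["400m"]]$amp,
                                        function(a) a * 2)
  s1 <- generate_session(p1, 1, cond400(), n_sprints = 4)
  s2 <- generate_session(p2, 1, cond400(), n_sprints = 4)
  for (site in c("nirs_muscle", "nirs_cerebral")) {
    for (ch in c("o2hb_uM", "hhb_uM", "tsi_pct")) {
      e1 <- s1[[site]][[ch]] - s1[[site]][[ch]][1]
      e2 <- s2[[site]][[ch]] - s2[[site]][[ch]][1]
      expect_equal(e2, 2 * e1, tolerance = 1e-9,
                   info = paste(site, ch))
    }
  }
})

test_that("noiseless per-sprint power decays geometrically and monotonically", {
  p <- noiseless_params()
  s <- generate_session(p, 1, cond400(), n_sprints = 8)
  expect_equal(s$truth$sprint_mean_power_w,
               p$power_best_w * (1 - p$power_decrement_frac)^(0:7))
  expect_true(all(diff(s$truth$sprint_mean_power_w) < 0))
})

test_that("cadence crosses the failure threshold only in the final sprint", {
  p <- noiseless_params()
  s <- generate_session(p, 1, cond400(), n_sprints = 7)
  on <- s$truth$sprint_onsets_s
  for (k in 1:7) {
    w <- s$cadence$time_s >= on[k] & s$cadence$time_s <= on[k] + 10
    mins <- min(s$cadence$cadence_rpm[w])
    if (k < 7) expect_gt(mins, 70) else expect_lt(mins, 70)
  }
})

test_that("invalid generator requests error; low draws re-draw with warning", {
  p <- synth_params()
  expect_error(generate_session(p, 1, cond400(), n_sprints = 0), ">= 1")
  expect_error(generate_session(p, 1, cond400(), n_sprints = 2), "floor")
  expect_error(rsa_protocol(sprint_s = -1), "positive")
  expect_error(synth_params(power_decrement_frac = 1), "power_decrement")
  set.seed(4)
  expect_warning(sprintnirs:::draw_n_sprints(3, 4), "re-drawing")
})

test_that("fio2 above room air is flagged", {
  expect_warning(rsa_condition("sea", 0.3), "room air")
  expect_silent(rsa_condition("400m", 0.209))
})

test_that("session writer round-trips streams losslessly through TSV", {
  p <- noiseless_params()
  s <- generate_session(p, 1, cond400(), n_sprints = 4)
  dir <- withr::local_tempdir()
  files <- write_session(s, dir)
  expect_true(all(file.exists(files)))
  back <- utils::read.table(file.path(dir, "S01_400m_nirs_muscle.tsv"),
                            header = TRUE, sep = "\t")
  expect_equal(back$hhb_uM, s$nirs_muscle$hhb_uM, tolerance = 1e-12)
})
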