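test_that("task schedule has the required condition counts and duration", {
  s <- generate_task_schedule(96, 30, 18, seed = 3)
  expect_equal(nrow(s), 96)
  expect_equal(sum(s$valence == "negative" & s$instruction == "reappraise"), 30)
  expect_equal(sum(s$valence == "negative" & s$instruction == "attend"), 18)
  expect_equal(sum(s$valence == "neutral"), 48)
  expect_true(all(s$valence == "neutral" | s$instruction %in%
                    c("attend", "reappraise")))
  expect_false(any(s$valence == "neutral" & s$instruction == "reappraise"))
  # total duration 2112 s = 1056 volumes at TR 2 s
  expect_equal(max(s$onset) + 22, 96 * 22)
  expect_equal((96 * 22) / 2, 1056)
  # rating windows are non-overlapping and inside the trial
  expect_true(all(s$rating_onset >= s$onset & s$rating_end <= s$onset + 22))
  expect_true(all(diff(sort(s$rating_onset)) >= 8))
})

test_that("task schedule is seeded and validates its arguments", {
  expect_identical(generate_task_schedule(24, 8, 5, seed = 9),
                   generate_task_schedule(24, 8, 5, seed = 9))
  s1 <- generate_task_schedule(24, 8, 5, seed = 1)
  s2 <- generate_task_schedule(24, 8, 5, seed = 2)
  expect_false(identical(s1$valence, s2$valence))
  expect_error(generate_task_schedule(10, -1, 3), "non-negative")
  expect_error(generate_task_schedule(10, 8, 5), "exceed")
})

test_that("synthetic config enforces the schedule/volume invariant", {
  expect_error(synthetic_config(n_trials = 96, n_volumes = 1000),
               "must match the task schedule")
  cfg <- synthetic_config()
  expect_equal(cfg$n_volumes, 1056L)
  expect_equal(cfg$n_mdd, 17L)
  expect_equal(cfg$n_ctrl, 14L)
})

test_that("noiseless uniform-loading BOLD makes every voxel the global component", {
  cfg <- small_config(noise_sd = 0, loading_sd = 0, background_loading = 1,
                      layer_loadings = list(interoceptive = c(ctrl = 1, mdd = 1),
                                            exteroceptive = c(ctrl = 1, mdd = 1),
                                            mental = c(ctrl = 1, mdd = 1)))
  b <- generate_bold(cfg, "mdd", seed = 4)
  m <- voxel_matrix(b)
  expect_lt(max(abs(sweep(m, 2, m[1, ]))), 1e-10)
  expect_lt(abs(sd(m[1, ]) - 1), 1e-8)
})

test_that("generate_bold is bit-identical under the same seed", {
  cfg <- small_config(seed = 8)
  b1 <- generate_bold(cfg, "ctrl", seed = 21)
  b2 <- generate_bold(cfg, "ctrl", seed = 21)
  expect_identical(b1$data, b2$data)
  b3 <- generate_bold(cfg, "ctrl", seed = 22)
  expect_false(identical(b1$data, b3$data))
})

test_that("noiseless pipeline GSCORR equals the analytic loading-implied value", {
  cfg <- small_config(noise_sd = 0, seed = 6)
  for (grp in c("mdd", "ctrl")) {
    b <- generate_bold(cfg, grp, seed = 31)
    truth <- attr(b, "truth")$gscorr
    est <- layer_gscorr(b)
    mrg <- merge(est, truth, by.x = "layer", by.y = "region")
    expect_gt(nrow(mrg), 2)
    expect_lt(max(abs(mrg$z.x - mrg$z.y)), 1e-6)
  }
})

test_that("elevated MDD mental loading raises mean mental GSCORR over cohorts", {
  cfg <- synthetic_config(n_trials = 24, n_reappraise_neg = 8,
                          n_attend_neg = 5, seed = 1)
  diffs <- vapply(1:20, function(s) {
    sim <- simulate_layer_gscorr(cfg, seed = 500 + s, apply_filter = FALSE)
    d <- sim[sim$layer == "mental", ]
    mean(d$z[d$group == "mdd"]) - mean(d$z[d$group == "ctrl"])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.85)
})

test_that("behavioural sampler hits the uniform and saturation limits", {
  flat <- behavior_coefs(matrix(0, 3, 5), reference = "2")
  z <- c(interoceptive = 0, exteroceptive = 0, mental = 0)
  r <- generate_behavior(z, "ctrl", flat, 10000, seed = 2)
  freq <- tabulate(r, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000)))

  sat <- behavior_coefs(rbind(c(20, 0, 0, 0, 0), rep(0, 5), rep(0, 5)),
                        reference = "2")
  r2 <- generate_behavior(z, "ctrl", sat, 2000, seed = 3)
  expect_gt(mean(r2 == 1), 0.99)

  bad <- behavior_coefs(rbind(c(Inf, 0, 0, 0, 0), rep(0, 5), rep(0, 5)),
                        reference = "2")
  expect_error(generate_behavior(z, "ctrl", bad, 10), "non-finite")
})

test_that("behavioural frequencies converge to the softmax probabilities", {
  cf <- default_behavior_coefs()$negative_attend
  z <- c(interoceptive = 0.1, exteroceptive = 0.3, mental = 0.2)
  p <- gstopo:::softmax_probs(cf, c(1, z, 1))
  r <- generate_behavior(z, "mdd", cf, 10000, seed = 11)
  freq <- tabulate(r, 4) / 10000
  expect_true(all(abs(freq - p) < 3 * sqrt(p * (1 - p) / 10000)))
})

test_that("default cohort reproduces the study dimensions", {
  cfg <- synthetic_config(seed = 2)
  coh <- generate_cohort(cfg)
  expect_equal(sum(coh$subjects$group == "mdd"), 17)
  expect_equal(sum(coh$subjects$group == "ctrl"), 14)
  expect_length(coh$bold, 31)
  expect_true(all(vapply(coh$bold, n_volumes, numeric(1)) == 1056))
  expect_gt(mean(coh$subjects$hamd[coh$subjects$group == "mdd"]),
            max(coh$subjects$hamd[coh$subjects$group == "ctrl"]))
  # behavioural table covers all subjects and conditions
  expect_setequal(unique(coh$trials$subject), coh$subjects$subject)
  rm(coh); gc(verbose = FALSE)
})

test_that("cohort subject tables and truth are seed-reproducible", {
  cfg <- small_config(seed = 13)
  c1 <- generate_cohort(cfg, include_bold = FALSE)
  c2 <- generate_cohort(cfg, include_bold = FALSE)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$truth, c2$truth)
  # truth matches the loading draws used with full BOLD generation
  c3 <- generate_cohort(cfg, include_bold = TRUE)
  expect_equal(c1$truth, c3$truth)
})

test_that("region-level fast path matches the voxel pipeline distributionally", {
  cfg <- small_config(seed = 3, n_mdd = 5, n_ctrl = 5)
  # same seeds: identical loading draws, so subject-level z agree closely
  # (they differ only through region-mean noise realisations)
  sim <- simulate_layer_gscorr(cfg, seed = cfg$seed, apply_filter = FALSE)
  full <- do.call(rbind, lapply(seq_len(10), function(i) {
    grp <- c(rep("mdd", 5), rep("ctrl", 5))[i]
    b <- generate_bold(cfg, grp, seed = gstopo:::subject_seed(cfg$seed, i))
    b <- discard_initial_volumes(b, 2)
    lg <- layer_gscorr(b)
    lg$subject <- sprintf("sub-%02d", i)
    lg
  }))
  mrg <- merge(sim, full, by = c("subject", "layer"))
  expect_equal(nrow(mrg), 30)
  expect_lt(max(abs(mrg$z.x - mrg$z.y)), 0.25)
  expect_gt(cor(mrg$z.x, mrg$z.y), 0.95)
})
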