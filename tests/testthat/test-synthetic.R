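test_that("config invariants are enforced", {
  expect_error(small_config(n_subtypes = 2, true_fractions = c(0.7, 0.2)),
               "sum to 1")
  expect_error(small_config(noise_sd = -1), "noise_sd")
  bad_roi <- default_roi_table()
  bad_roi$mean_mm3[1] <- -5
  expect_error(synth_config(roi_table = bad_roi), "positive")
  cfg <- small_config()
  expect_error(
    synth_config(roi_table = cfg$roi_table, event_grid = cfg$event_grid,
                 true_sequences = cfg$true_sequences,
                 true_fractions = c(0.75, 0.25),
                 syndrome_enrichment = rbind(c(0.5, 0.4, 0.4),
                                             c(0.2, 0.2, 0.6))),
    "summing to 1")
})

test_that("generation is deterministic: same seed, byte-identical files", {
  cfg <- small_config(n_controls = 40, n_patients = 40)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  s7a <- simulate_cohort(cfg, seed = 7)
  s7b <- simulate_cohort(cfg, seed = 7)
  s8 <- simulate_cohort(cfg, seed = 8)
  write_cohort(s7a$cohort, s7a$truth, d1)
  write_cohort(s7b$cohort, s7b$truth, d2)
  write_cohort(s8$cohort, s8$truth, d3)
  f1 <- readBin(file.path(d1, "cohort.csv"), "raw", 1e7)
  f2 <- readBin(file.path(d2, "cohort.csv"), "raw", 1e7)
  f3 <- readBin(file.path(d3, "cohort.csv"), "raw", 1e7)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  back <- read_cohort(d1)
  expect_equal(nrow(back$cohort), nrow(s7a$cohort))
  expect_true("truth" %in% names(back))
})

test_that("noise-free patients at stage 0 sit exactly on the covariate-predicted mean", {
  cfg <- small_config(n_controls = 30, n_patients = 30, noise_sd = 0,
                      stage_distribution = c(1, rep(0, 12)))
  b <- simulate_baseline(cfg, seed = 1)
  pat <- b$cohort[b$cohort$group == "patient", ]
  shift <- sustainr:::covariate_shift(cfg, pat)
  for (r in cfg$roi_table$roi) {
    mean_r <- cfg$roi_table$mean_mm3[cfg$roi_table$roi == r]
    expect_equal(pat[[paste0("roi_", r)]], mean_r + shift[, r],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("control volumes honour the configured baseline mean (law of large numbers)", {
  cfg <- small_config(n_controls = 10000, n_patients = 20,
                      covariate_effects = tibble::tibble(
                        roi = paste0("r", 1:6), age = 0, sex_male = 0,
                        tiv = 0, field_3t = 0, manu_ge = 0, manu_philips = 0))
  b <- simulate_baseline(cfg, seed = 3)
  ctrl <- b$cohort[b$cohort$group == "control", ]
  for (i in seq_len(6)) {
    r <- cfg$roi_table$roi[i]
    se <- cfg$roi_baseline_sd[[r]] / sqrt(10000)
    expect_lt(abs(mean(ctrl[[paste0("roi_", r)]]) -
                    cfg$roi_table$mean_mm3[i]), 3 * se)
  }
})

test_that("patient z-scores at the end stage sit on the trajectory endpoint", {
  cfg <- small_config(n_controls = 50, n_patients = 2000, n_subtypes = 1,
                      stage_distribution = c(rep(0, 12), 1))
  b <- simulate_baseline(cfg, seed = 4)
  pat <- b$cohort[b$cohort$group == "patient", ]
  shift <- sustainr:::covariate_shift(cfg, pat)
  E <- cfg$event_grid$n_events
  for (i in c(1, 4)) {
    r <- cfg$roi_table$roi[i]
    z <- -(pat[[paste0("roi_", r)]] - cfg$roi_table$mean_mm3[i] -
             shift[, r]) / cfg$roi_baseline_sd[[r]]
    g_end <- trajectory_value(cfg$true_sequences[[1]], cfg$event_grid, r, E)
    expect_lt(abs(mean(z) - g_end), 3 * cfg$noise_sd / sqrt(2000))
  }
})

test_that("follow-up stage arithmetic: rate x gap, never decreasing, capped at E", {
  cfg <- small_config(
    n_controls = 10, n_patients = 60,
    followup_spec = list(gap_mean = 1, gap_sd = 0, p_followup = 1,
                         rates = c(RS = 2, cortical = 2, subcortical = 2),
                         stage_noise_lambda = 0)
  )
  b <- simulate_baseline(cfg, seed = 5)
  b <- attach_syndromes_and_scores(b$cohort, b$truth, cfg, seed = 6)
  f <- simulate_followups(b$cohort, b$truth, cfg, seed = 7)
  E <- cfg$event_grid$n_events
  tr <- tidyr::pivot_wider(f$truth, id_cols = "subject_id",
                           names_from = "visit",
                           values_from = "true_stage")
  expect_equal(tr$`1`, pmin(E, tr$`0` + 2))

  cfg0 <- small_config(
    n_controls = 10, n_patients = 40,
    followup_spec = list(gap_mean = 1, gap_sd = 0.3, p_followup = c(1, 1),
                         rates = c(RS = 0, cortical = 0, subcortical = 0),
                         stage_noise_lambda = 0)
  )
  b0 <- simulate_baseline(cfg0, seed = 8)
  b0 <- attach_syndromes_and_scores(b0$cohort, b0$truth, cfg0, seed = 9)
  f0 <- simulate_followups(b0$cohort, b0$truth, cfg0, seed = 10)
  stable <- dplyr::summarise(dplyr::group_by(f0$truth, subject_id),
                             same = dplyr::n_distinct(true_stage) == 1)
  expect_true(all(stable$same))
  expect_error(small_config(followup_spec = list(
    gap_mean = 1, gap_sd = 0.1, p_followup = 1,
    rates = c(RS = -1, cortical = 1, subcortical = 1),
    stage_noise_lambda = 0)), ">= 0")
})

test_that("true stages never decrease and subtypes never change across visits", {
  cfg <- small_config(n_controls = 10, n_patients = 80)
  sim <- simulate_cohort(cfg, seed = 11)
  chk <- dplyr::summarise(
    dplyr::group_by(dplyr::arrange(sim$truth, subject_id, visit), subject_id),
    mono = all(diff(true_stage) >= 0),
    one_subtype = dplyr::n_distinct(true_subtype) == 1
  )
  expect_true(all(chk$mono))
  expect_true(all(chk$one_subtype))
})

test_that("identity enrichment copies the subtype into the syndrome label", {
  cfg <- small_config(n_controls = 10, n_patients = 200,
                      syndromes = c("s1", "s2"),
                      syndrome_enrichment = diag(2))
  b <- simulate_baseline(cfg, seed = 12)
  b <- attach_syndromes_and_scores(b$cohort, b$truth, cfg, seed = 13)
  pat <- b$cohort[b$cohort$group == "patient", ]
  tr <- b$truth[match(pat$subject_id, b$truth$subject_id), ]
  expect_equal(pat$syndrome, paste0("s", tr$true_subtype))
})

test_that("default syndrome enrichment reproduces the configured confusion by Monte Carlo", {
  cfg <- small_config(n_controls = 10, n_patients = 10000)
  b <- simulate_baseline(cfg, seed = 14)
  b <- attach_syndromes_and_scores(b$cohort, b$truth, cfg, seed = 15)
  pat <- b$cohort[b$cohort$group == "patient", ]
  tr <- b$truth[match(pat$subject_id, b$truth$subject_id), ]
  emp <- prop.table(table(tr$true_subtype, pat$syndrome), margin = 1)
  for (s in 1:2) {
    for (j in seq_along(cfg$syndromes)) {
      expect_lt(abs(emp[s, cfg$syndromes[j]] - cfg$syndrome_enrichment[s, j]),
                0.02)
    }
  }
})

test_that("clinical scores follow the configured stage slope exactly when noise-free", {
  sm <- default_score_models()
  sm$noise_sd <- 0
  cfg <- small_config(n_controls = 10, n_patients = 300, score_models = sm)
  b <- simulate_baseline(cfg, seed = 16)
  b <- attach_syndromes_and_scores(b$cohort, b$truth, cfg, seed = 17)
  pat <- b$cohort[b$cohort$group == "patient", ]
  tr <- b$truth[match(pat$subject_id, b$truth$subject_id), ]
  m <- sm[sm$score == "psprs_total", ]
  expected <- pmin(pmax(m$intercept + m$stage_slope * tr$true_stage +
                          m$subtype_offset * (tr$true_subtype == 2),
                        m$min), m$max)
  expect_equal(pat$psprs_total, expected)
  s10 <- pat$psprs_total[tr$true_stage == 10 & tr$true_subtype == 1]
  s0 <- pat$psprs_total[tr$true_stage == 0 & tr$true_subtype == 1]
  if (length(s10) && length(s0)) {
    expect_equal(unique(s10) - unique(s0), 10 * m$stage_slope)
  }
})

test_that("scores stay inside their published ranges", {
  cfg <- small_config(n_controls = 10, n_patients = 400)
  sim <- simulate_cohort(cfg, seed = 18)
  pat <- sim$cohort[sim$cohort$group == "patient", ]
  rng <- default_score_models()
  for (r in seq_len(nrow(rng))) {
    v <- pat[[rng$score[r]]]
    expect_true(all(v >= rng$min[r] & v <= rng$max[r]))
  }
})
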