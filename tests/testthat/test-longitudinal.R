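`%||%` <- function(a, b) if (is.null(a)) b else a

mk_pairs <- function(df) {
  # df: per-pair shorthand; expand into the visit_pairs column set
  tibble::tibble(
    subject_id = df[["id"]],
    visit_earlier = 0L, visit_later = 1L,
    dt_years = df[["dt"]] %||% rep(1, nrow(df)),
    subtype_earlier = df[["sub1"]], subtype_later = df[["sub2"]],
    stage_earlier = df[["st1"]], stage_later = df[["st2"]],
    expected_earlier = df[["st1"]], expected_later = df[["st2"]],
    subtypable_earlier = df[["ok1"]] %||% rep(TRUE, nrow(df)),
    subtypable_later = df[["ok2"]] %||% rep(TRUE, nrow(df)),
    syndrome = df[["syn"]] %||% rep("RS", nrow(df))
  )
}

test_that("visit pairs are consecutive, time-ordered and carry syndrome labels", {
  a <- tibble::tibble(
    subject_id = rep(c("p1", "p2"), c(3, 1)),
    visit = c(0, 1, 2, 0),
    days_since_baseline = c(0, 365.25, 730.5, 0),
    ml_subtype = c(1, 1, 2, 1), ml_stage = c(2, 4, 5, 3),
    expected_stage = c(2.2, 4.1, 4.9, 3.0),
    subtypable = TRUE
  )
  cohort <- tibble::tibble(subject_id = c("p1", "p1", "p1", "p2"),
                           visit = c(0, 1, 2, 0),
                           syndrome = "RS")
  pairs <- visit_pairs(a, cohort)
  expect_equal(nrow(pairs), 2)  # p1 contributes two consecutive pairs
  expect_equal(pairs$dt_years, c(1, 1), tolerance = 1e-9)
  expect_equal(pairs$visit_earlier, c(0, 1))
  a_bad <- a
  a_bad$days_since_baseline[2] <- -10
  expect_error(visit_pairs(a_bad, cohort), "Non-positive")
})

test_that("subtype stability counts matches, stage-0 entries, and builds the transition table", {
  p <- mk_pairs(tibble::tibble(id = paste0("s", 1:4),
                               sub1 = c(1, 1, 1, 1), sub2 = c(1, 1, 1, 2),
                               st1 = c(3, 4, 5, 6), st2 = c(4, 5, 6, 7)))
  st <- subtype_stability(p)
  expect_equal(st$proportion, 0.75)
  expect_equal(st$n_consistent, 3)

  all_same <- mk_pairs(tibble::tibble(id = paste0("s", 1:5),
                                      sub1 = rep(2, 5), sub2 = rep(2, 5),
                                      st1 = 1:5, st2 = 2:6))
  expect_equal(subtype_stability(all_same)$proportion, 1)

  # stage-0 scan progressing into a subtype is consistent; an end-stage
  # exit is not
  p2 <- mk_pairs(tibble::tibble(
    id = c("a", "b"), sub1 = c(1, 1), sub2 = c(1, 1),
    st1 = c(0, 5), st2 = c(3, 12),
    ok1 = c(FALSE, TRUE), ok2 = c(TRUE, FALSE)))
  st2 <- subtype_stability(p2)
  expect_equal(st2$proportion, 0.5)
  tr <- st2$transitions
  expect_equal(tr["normal_appearing", "subtype_1"], 1)
  expect_equal(tr["subtype_1", "normal_appearing"], 1)
})

test_that("stage progression proportions sum to one and split by group", {
  p <- mk_pairs(tibble::tibble(id = paste0("s", 1:3),
                               sub1 = 1, sub2 = 1,
                               st1 = c(3, 4, 6), st2 = c(5, 4, 2)))
  sp <- stage_progression(p)
  expect_equal(c(sp$progressed, sp$unchanged, sp$regressed),
               c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(sp$progressed + sp$unchanged + sp$regressed, 1)
  all_up <- mk_pairs(tibble::tibble(id = paste0("s", 1:4), sub1 = 1,
                                    sub2 = 1, st1 = 1:4, st2 = 3:6))
  expect_equal(stage_progression(all_up)$progressed, 1)
  by_sub <- stage_progression(
    mk_pairs(tibble::tibble(id = paste0("s", 1:4),
                            sub1 = c(1, 1, 2, 2), sub2 = c(1, 1, 2, 2),
                            st1 = c(1, 2, 1, 2), st2 = c(2, 1, 2, 3))),
    by = "subtype_earlier")
  expect_equal(nrow(by_sub), 2)
  expect_equal(by_sub$progressed_or_same, c(0.5, 1))
})

test_that("progression rates are stages-per-year with a Welch comparison", {
  p <- mk_pairs(tibble::tibble(id = "s1", sub1 = 1, sub2 = 1,
                               st1 = 10, st2 = 12, dt = 1))
  r <- progression_rate(p, "syndrome")
  expect_equal(r$rates$mean_rate, 2)
  p_bad <- p
  p_bad$dt_years <- 0
  expect_error(progression_rate(p_bad, "syndrome"), "dt_years > 0")

  withr::with_seed(9, {
    n <- 100
    fast <- tibble::tibble(id = sprintf("f%03d", 1:n), sub1 = 1, sub2 = 1,
                           st1 = 5, st2 = 5 + round(rnorm(n, 1.86, 1.5)),
                           dt = 1, syn = "RS")
    slow <- tibble::tibble(id = sprintf("s%03d", 1:n), sub1 = 1, sub2 = 1,
                           st1 = 5, st2 = 5 + round(rnorm(n, 0.66, 1.5)),
                           dt = 1, syn = "subcortical")
  })
  pr <- progression_rate(mk_pairs(dplyr::bind_rows(fast, slow)), "syndrome",
                         compare = c("RS", "subcortical"))
  diff <- pr$comparison$mean_a - pr$comparison$mean_b
  se <- sqrt(sum(pr$rates$sd_rate^2 / pr$rates$n))
  expect_lt(abs(diff - (1.86 - 0.66)), 3 * se)
  expect_gt(pr$comparison$statistic, 0)
})

test_that("noise-free monotone truth gives progressed-or-same of exactly one", {
  cfg <- small_config(n_controls = 100, n_patients = 60, noise_sd = 0)
  sim <- simulate_cohort(cfg, seed = 21)
  fit <- sustain_fit(cfg$event_grid, cfg$true_sequences, cfg$true_fractions)
  prep <- suppressMessages(prepare_biomarkers(sim$cohort, d_threshold = 0.3))
  a <- suppressMessages(assign_cohort(prep$panel, fit))
  pairs <- visit_pairs(a[a$group == "patient", ], sim$cohort)
  # with zero observation noise the assigned stages inherit the monotone truth
  expect_equal(stage_progression(pairs)$progressed_or_same, 1)
})
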