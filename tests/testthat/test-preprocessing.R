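test_that("hemisphere combining sums pairs, passes midline regions, flags orphans", {
  d <- tibble::tibble(roi_thal_L = 5000, roi_thal_R = 5200, roi_pons = 14000)
  out <- combine_hemispheres(d)
  expect_equal(out$roi_thal, 10200)
  expect_equal(out$roi_pons, 14000)
  expect_false(any(c("roi_thal_L", "roi_thal_R") %in% names(out)))
  expect_error(combine_hemispheres(tibble::tibble(roi_amyg_L = 800)),
               "roi_amyg_R")
})

make_ctrl_cohort <- function(n, age_slope = 0, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      subject_id = sprintf("c%03d", seq_len(n)), visit = 0L,
      days_since_baseline = 0, group = "control", syndrome = "control",
      age = runif(n, 45, 85), sex = sample(c("F", "M"), n, TRUE),
      tiv_mm3 = rnorm(n, 1.4e6, 1e5),
      field_strength = sample(c(1.5, 3), n, TRUE),
      manufacturer = sample(c("Siemens", "GE", "Philips"), n, TRUE),
      cohort = "cohort_1",
      roi_a = 10000 + age_slope * (age - 65) + rnorm(n, 0, 400),
      roi_b = 5000 + rnorm(n, 0, 250)
    )
  })
}

test_that("the adjuster recovers injected covariate effects on controls", {
  d <- make_ctrl_cohort(400, age_slope = -20, seed = 2)
  adj <- fit_covariate_adjuster(d)
  sm <- summary(stats::lm(d$roi_a ~ d$age))
  se <- sm$coefficients["d$age", "Std. Error"]
  expect_lt(abs(adj$coefs["age", "roi_a"] - (-20)), 3 * se)
  # no effect injected on roi_b: every non-intercept coefficient near zero
  d0 <- make_ctrl_cohort(400, age_slope = 0, seed = 3)
  adj0 <- fit_covariate_adjuster(d0)
  fit_b <- stats::lm(roi_b ~ age + sex + tiv_mm3 + factor(field_strength) +
                       manufacturer, data = d0)
  ses <- summary(fit_b)$coefficients[-1, "Std. Error"]
  expect_true(all(abs(adj0$coefs[-1, "roi_b"]) < 3 * max(ses) + 1e-9))
})

test_that("too few controls or degenerate designs are rejected", {
  d <- make_ctrl_cohort(4)
  expect_error(suppressWarnings(fit_covariate_adjuster(d[1, ])), "Too few")
  expect_error(fit_covariate_adjuster(d), "Too few")
})

test_that("adjustment centres on the control reference and handles unseen levels", {
  d <- make_ctrl_cohort(300, seed = 4)
  adj <- fit_covariate_adjuster(d)
  adjusted <- apply_adjuster(adj, d)
  # residual-plus-reference form: control means are preserved
  expect_equal(mean(adjusted$roi_a), mean(d$roi_a), tolerance = 1e-8)
  new <- d[1, ]
  new$manufacturer <- "Canon"
  expect_warning(apply_adjuster(adj, new), "Unseen level")
})

test_that("covariate adjustment removes an injected age slope", {
  d <- make_ctrl_cohort(400, age_slope = -25, seed = 5)
  adj <- fit_covariate_adjuster(d)
  adjusted <- apply_adjuster(adj, d)
  t_raw <- summary(stats::lm(d$roi_a ~ d$age))$coefficients["d$age", "t value"]
  t_adj <- summary(stats::lm(adjusted$roi_a ~ adjusted$age))$coefficients[
    "adjusted$age", "t value"]
  expect_gt(abs(t_raw), 5)
  expect_lt(abs(t_adj), 2)
})

test_that("Cohen's d matches hand computations and guards degenerate input", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  withr::with_seed(6, {
    a <- rnorm(50)
  })
  sp <- sd(a)
  expect_equal(cohens_d(a + sp, a), 1, tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "Pooled variance")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})


test_that("effect-size selection keeps strong and drops weak biomarkers", {
  hits <- vapply(1:100, function(seed) {
    sel <- select_biomarkers(make_selection_cohort(seed), threshold = 0.6)
    setequal(selected_biomarkers(sel), paste0("s", 1:5))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("selection threshold edge cases behave as documented", {
  d <- make_selection_cohort(1)
  expect_equal(nrow(dplyr::filter(select_biomarkers(d, threshold = 0), selected)),
               10)
  expect_error(select_biomarkers(d, threshold = Inf), "threshold")
  sel <- select_biomarkers(d, threshold = 0.6)
  expect_false(is.unsorted(rev(sel$d)))  # descending d
})

test_that("selection is invariant to affine rescaling of a region's units", {
  d <- make_selection_cohort(2)
  d2 <- d
  d2$roi_s1 <- d2$roi_s1 * 1000 + 5
  s1 <- select_biomarkers(d, threshold = 0.6)
  s2 <- select_biomarkers(d2, threshold = 0.6)
  expect_equal(s1$d, s2$d, tolerance = 1e-12)
  expect_equal(selected_biomarkers(s1), selected_biomarkers(s2))
})

test_that("z-scoring flips the sign and standardises against adjusted controls", {
  d <- make_ctrl_cohort(300, seed = 7)
  adj <- fit_covariate_adjuster(d)
  adjusted <- apply_adjuster(adj, d)
  panel <- compute_zscores(adjusted, adj, c("a", "b"))
  Z <- panel_matrix(panel, "control")
  expect_equal(unname(colMeans(Z)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1), tolerance = 1e-10)
  # a patient 2 control SDs BELOW the control mean scores +2
  pat <- adjusted[1, ]
  pat$group <- "patient"
  pat$roi_a <- adj$control_mean[["roi_a"]] - 2 * adj$control_sd[["roi_a"]]
  pat$roi_b <- adj$control_mean[["roi_b"]]
  # volumes are already adjusted: re-adjustment must be bypassed
  p2 <- compute_zscores(pat, adj, c("a", "b"))
  expect_equal(unname(p2$z[1, "a"]), 2, tolerance = 1e-12)
  expect_equal(unname(p2$z[1, "b"]), 0, tolerance = 1e-12)
})

test_that("scans missing a selected region are excluded with a message", {
  d <- make_ctrl_cohort(100, seed = 8)
  adj <- fit_covariate_adjuster(d)
  adjusted <- apply_adjuster(adj, d)
  adjusted$roi_a[3] <- NA
  expect_message(panel <- compute_zscores(adjusted, adj, c("a", "b")),
                 "excluded")
  expect_equal(nrow(panel$z), 99)
})

test_that("the full preparation pipeline is reproducible bit-for-bit", {
  cfg <- small_config(n_controls = 60, n_patients = 60)
  sim <- simulate_cohort(cfg, seed = 9)
  p1 <- suppressMessages(prepare_biomarkers(sim$cohort))
  p2 <- suppressMessages(prepare_biomarkers(sim$cohort))
  expect_identical(p1$panel$z, p2$panel$z)
  expect_identical(p1$selection$d, p2$selection$d)
})
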