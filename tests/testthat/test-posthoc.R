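test_that("Welch t agrees between raw vectors, summary statistics, and stats::t.test", {
  withr::with_seed(1, {
    a <- rnorm(40, 1, 2)
    b <- rnorm(60, 0, 1)
  })
  from_vec <- welch_t(a, b)
  from_sum <- welch_t(mean(a), mean(b), sd_a = sd(a), n_a = 40,
                      sd_b = sd(b), n_b = 60)
  expect_equal(from_vec$statistic, from_sum$statistic, tolerance = 1e-10)
  expect_equal(from_vec$df, from_sum$df, tolerance = 1e-10)
  expect_equal(from_vec$p_value, from_sum$p_value, tolerance = 1e-10)
  tt <- stats::t.test(a, b)
  expect_equal(from_vec$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(from_vec$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_error(welch_t(1, 2, sd_a = 0, n_a = 10, sd_b = 0, n_b = 10),
               "not both zero")
})

test_that("Welch t reproduces the published subtype comparisons from summary statistics", {
  # PSP rating scale: cortical 30.3 (16.9, n=104) vs subcortical 37.0 (13.6, n=302)
  psprs <- welch_t(30.3, 37.0, sd_a = 16.9, n_a = 104, sd_b = 13.6, n_b = 302)
  expect_equal(round(psprs$statistic, 1), -3.7)
  # MMSE: 24.9 (4.2) vs 25.5 (3.6)
  mmse <- welch_t(24.9, 25.5, sd_a = 4.2, n_a = 104, sd_b = 3.6, n_b = 302)
  expect_equal(round(mmse$statistic, 1), -1.3)
})

test_that("Pearson chi-square matches the textbook oracle and hand values", {
  oracle_chi2 <- function(t) {
    e <- outer(rowSums(t), colSums(t)) / sum(t)
    sum((t - e)^2 / e)
  }
  expect_equal(chi_square(rbind(c(10, 0), c(0, 10)), pairwise = FALSE)$statistic,
               20)
  prop <- rbind(c(30, 60), c(10, 20))  # perfectly proportional
  expect_equal(chi_square(prop, pairwise = FALSE)$statistic, 0,
               tolerance = 1e-12)
  withr::with_seed(2, {
    for (i in 1:10) {
      t <- matrix(rpois(6, 30) + 1, 2, 3)
      expect_equal(chi_square(t, pairwise = FALSE)$statistic, oracle_chi2(t),
                   tolerance = 1e-9)
    }
  })
})

test_that("pairwise post-hoc comparisons cover every row pair with Bonferroni adjustment", {
  counts <- rbind(c(280, 65), c(8, 36), c(14, 3))
  res <- suppressWarnings(chi_square(counts, family_size = 11))
  expect_equal(nrow(res$pairwise), 3)
  expect_equal(res$pairwise$p_adjusted,
               pmin(1, res$pairwise$p_value * 3))
  expect_true(res$significant_corrected)
})

test_that("the clinical-score linear model recovers injected stage effects", {
  sim_scores <- function(seed, stage_slope = 0.5, subtype_offset = 0) {
    withr::with_seed(seed, {
      n <- 150
      tibble::tibble(
        ml_subtype = sample(1:2, n, TRUE, prob = c(0.75, 0.25)),
        expected_stage = runif(n, 0, 40),
        age = rnorm(n, 68, 7),
        sex = sample(c("F", "M"), n, TRUE),
        subtypable = TRUE,
        score = 20 + stage_slope * expected_stage +
          subtype_offset * (ml_subtype == 2) + rnorm(n, 0, 4)
      )
    })
  }
  hits_stage <- hits_subtype <- logical(100)
  for (i in 1:100) {
    tab <- clinical_score_lm(sim_scores(i), "score")
    st <- tab[tab$term == "stage", ]
    hits_stage[i] <- abs(st$estimate - 0.5) < 3 * st$std_error
    hits_subtype[i] <- abs(tab$statistic[tab$term == "subtype_cortical"]) < 2
  }
  expect_gte(mean(hits_stage), 0.95)
  expect_gte(mean(hits_subtype), 0.95)
  tab <- clinical_score_lm(sim_scores(1, subtype_offset = 0), "score")
  expect_equal(tab$direction[tab$term == "stage"], "worsens with stage")
})

test_that("rank-deficient score models and short data are rejected", {
  d <- tibble::tibble(
    ml_subtype = rep(1:2, each = 15),
    expected_stage = runif(30, 0, 40),
    age = rnorm(30, 68, 7),
    sex = rep(c("F", "M"), each = 15),  # perfectly collinear with subtype
    subtypable = TRUE,
    score = rnorm(30, 20, 5)
  )
  expect_error(clinical_score_lm(d, "score"), "rank deficient")
  expect_error(clinical_score_lm(d[1:10, ], "score"), ">= 20")
})

test_that("the subtype-covariate logistic regression behaves under null and signal", {
  null_z <- vapply(1:100, function(seed) {
    withr::with_seed(seed, {
      d <- tibble::tibble(
        ml_subtype = sample(1:2, 200, TRUE),
        expected_stage = runif(200, 0, 40),
        age = rnorm(200, 68, 7),
        subtypable = TRUE
      )
    })
    tab <- subtype_covariate_logit(d, covariates = c("expected_stage", "age"))
    tab$statistic[tab$term == "expected_stage"]
  }, numeric(1))
  expect_gte(mean(abs(null_z) < 2), 0.95)
  withr::with_seed(7, {
    d <- tibble::tibble(
      age = rnorm(400, 68, 7),
      expected_stage = runif(400, 0, 40),
      subtypable = TRUE
    )
    d$ml_subtype <- 1 + rbinom(400, 1, plogis(-13.6 + 0.2 * d$age))
  })
  tab <- subtype_covariate_logit(d, covariates = c("expected_stage", "age"))
  expect_lt(tab$p_value[tab$term == "age"], 0.05)
  d$ml_subtype <- 1
  expect_error(subtype_covariate_logit(d), "constant")
})

test_that("the two-factor stage ANOVA detects injected syndrome offsets", {
  withr::with_seed(3, {
    n <- 240
    syn <- sample(c("RS", "cortical", "subcortical"), n, TRUE,
                  prob = c(0.8, 0.12, 0.08))
    sub <- sample(1:2, n, TRUE, prob = c(0.75, 0.25))
    # analogue of mean stage 19.9 (Richardson) versus 7.4 (subcortical variant)
    mu <- c(RS = 19.9, cortical = 18.9, subcortical = 7.4)[syn]
    d <- tibble::tibble(syndrome = syn, ml_subtype = sub,
                        expected_stage = rnorm(n, mu, 9), subtypable = TRUE)
  })
  res <- stage_anova(d)
  expect_lt(res$anova$p_value[res$anova$term == "syndrome"], 0.001)
  est <- res$tukey$estimate[res$tukey$factor == "syndrome" &
                              res$tukey$contrast == "subcortical-RS"]
  expect_lt(est, 0)
  # all means equal -> both factors near-null F
  withr::with_seed(4, {
    d0 <- tibble::tibble(syndrome = sample(c("RS", "cortical"), 200, TRUE),
                         ml_subtype = sample(1:2, 200, TRUE),
                         expected_stage = rnorm(200, 15, 5),
                         subtypable = TRUE)
  })
  res0 <- stage_anova(d0)
  expect_true(all(res0$anova$p_value[1:2] > 0.01))
})

test_that("score proration applies the 80% completeness rule", {
  expect_equal(prorate_score(rep(2, 10), 10), 20)
  expect_equal(prorate_score(c(rep(2, 8), NA, NA), 10), 20)
  expect_true(is.na(prorate_score(c(rep(2, 7), NA, NA, NA), 10)))
  expect_equal(prorate_score(c(1, 2, 3, NA, NA), 5), NA_real_)
  expect_equal(prorate_score(c(1, 3, 2, 4), 5), 12.5)  # 4/5 = 80% complete
})
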