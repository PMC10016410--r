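sig_flags <- function(p, family_size) {
  tibble::tibble(
    significant_uncorrected = p < 0.05,
    significant_corrected = if (is.null(family_size)) NA else
      p < 0.05 / family_size,
    family_size = if (is.null(family_size)) NA_integer_ else
      as.integer(family_size)
  )
}

#' Welch two-sample t-test from vectors or summary statistics
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom,
#' `t = (mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b)`. Accepts either two
#' raw vectors or the six summary statistics, which makes the published
#' group summaries of a table directly checkable.
#'
#' @param a First group: numeric vector, or its mean when summary statistics
#'   are supplied.
#' @param b Second group: numeric vector or mean.
#' @param sd_a,n_a,sd_b,n_b Summary statistics; leave `NULL` to treat
#'   `a`/`b` as raw vectors.
#' @param family_size Optional multiple-comparison family size for the
#'   Bonferroni-corrected significance flag.
#' @return One-row tibble: means, `statistic`, `df`, `p_value`, and
#'   significance flags.
#' @examples
#' welch_t(30.3, 37.0, sd_a = 16.9, n_a = 104, sd_b = 13.6, n_b = 302)
#' @export
welch_t <- function(a, b, sd_a = NULL, n_a = NULL, sd_b = NULL, n_b = NULL,
                    family_size = NULL) {
  if (is.null(sd_a)) {
    if (length(a) < 2 || length(b) < 2) stop("Each group needs >= 2 values.")
    sd_a <- stats::sd(a); n_a <- length(a); a <- mean(a)
    sd_b <- stats::sd(b); n_b <- length(b); b <- mean(b)
  }
  if (n_a < 2 || n_b < 2) stop("Each group needs n >= 2.")
  if (sd_a < 0 || sd_b < 0 || (sd_a == 0 && sd_b == 0)) {
    stop("SDs must be non-negative and not both zero.")
  }
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  se <- sqrt(va + vb)
  t <- (a - b) / se
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  p <- 2 * stats::pt(-abs(t), df)
  dplyr::bind_cols(
    tibble::tibble(mean_a = a, mean_b = b, statistic = t, df = df,
                   p_value = p),
    sig_flags(p, family_size)
  )
}

#' Pearson chi-square test with pairwise post-hoc comparisons
#'
#' Pearson chi-square without continuity correction on an r x c contingency
#' table, plus post-hoc pairwise comparisons of every pair of rows (each a
#' 2 x c Pearson test) with Bonferroni-adjusted p-values.
#'
#' @param counts Matrix or table of counts (rows = groups).
#' @param pairwise Run the row-pairwise post-hoc comparisons? Default `TRUE`
#'   when there are more than two rows.
#' @param family_size Optional family size for the corrected flag on the
#'   omnibus test.
#' @return List with `statistic`, `df`, `p_value`, `expected`, significance
#'   flags, and (when requested) `pairwise`, a tibble of row-pair tests.
#' @examples
#' chi_square(rbind(c(280, 65), c(8, 36), c(14, 3)))
#' @export
chi_square <- function(counts, pairwise = nrow(counts) > 2,
                       family_size = NULL) {
  counts <- as.matrix(counts)
  test <- stats::chisq.test(counts, correct = FALSE)
  if (any(test$expected <= 0)) stop("All expected counts must be positive.")
  out <- list(statistic = unname(test$statistic),
              df = unname(test$parameter),
              p_value = test$p.value,
              expected = test$expected)
  out <- c(out, as.list(sig_flags(test$p.value, family_size)[1, ]))
  if (isTRUE(pairwise)) {
    combs <- utils::combn(nrow(counts), 2)
    pw <- purrr::map_dfr(seq_len(ncol(combs)), function(i) {
      rows <- combs[, i]
      sub <- stats::chisq.test(counts[rows, , drop = FALSE], correct = FALSE)
      tibble::tibble(row_a = rows[1], row_b = rows[2],
                     statistic = unname(sub$statistic),
                     df = unname(sub$parameter), p_value = sub$p.value)
    })
    pw$p_adjusted <- stats::p.adjust(pw$p_value, method = "bonferroni")
    out$pairwise <- pw
  }
  out
}

#' Linear model of a clinical score on subtype, stage, age and sex
#'
#' Ordinary least squares `score ~ subtype + stage + age + sex` over
#' subtypable scans, the standard model for asking whether a clinical scale
#' differs between subtypes once disease stage and demographics are
#' accounted for. The subtype enters as an indicator with the cortical
#' subtype coded 1, so a negative subtype coefficient on a
#' higher-is-worse scale means the subcortical subtype scores worse.
#'
#' @param data Data frame with the score column, `ml_subtype` (1 =
#'   subcortical reference, 2 = cortical), `expected_stage` (or `stage`),
#'   `age`, `sex`, and optionally `subtypable` (rows with `FALSE` are
#'   dropped).
#' @param score Name of the score column.
#' @param higher_is_worse Direction of the scale, default `TRUE` (set
#'   `FALSE` for MMSE/SEADL-like scales).
#' @param family_size Optional family size for corrected flags.
#' @return Tibble of coefficients (term, estimate, std_error, statistic,
#'   p_value, flags) with direction labels on the subtype and stage rows.
#' @export
clinical_score_lm <- function(data, score, higher_is_worse = TRUE,
                              family_size = NULL) {
  d <- tibble::as_tibble(data)
  if ("subtypable" %in% names(d)) d <- d[d$subtypable, ]
  stage_col <- if ("expected_stage" %in% names(d)) "expected_stage" else "stage"
  d <- d[stats::complete.cases(d[c(score, "ml_subtype", stage_col,
                                   "age", "sex")]), ]
  if (nrow(d) < 20) stop("Need >= 20 complete cases; got ", nrow(d), ".")
  d$subtype_cortical <- as.numeric(d$ml_subtype == 2)
  d$stage <- d[[stage_col]]
  d$sex <- factor(d$sex)
  fml <- stats::as.formula(paste(score, "~ subtype_cortical + stage + age + sex"))
  fit <- stats::lm(fml, data = d)
  if (anyNA(stats::coef(fit))) {
    stop("Model is rank deficient (collinear terms): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  tab <- tibble::tibble(
    term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
    statistic = sm[, 3], p_value = sm[, 4]
  )
  tab <- dplyr::bind_cols(tab, sig_flags(tab$p_value, family_size))
  # direction labels: which subtype is worse / how the score moves with stage
  bsub <- tab$estimate[tab$term == "subtype_cortical"]
  bstage <- tab$estimate[tab$term == "stage"]
  worse_high <- if (higher_is_worse) 1 else -1
  tab$direction <- NA_character_
  tab$direction[tab$term == "subtype_cortical"] <-
    if (bsub * worse_high > 0) "cortical worse" else "subcortical worse"
  tab$direction[tab$term == "stage"] <-
    if (bstage * worse_high > 0) "worsens with stage" else
      "improves with stage"
  tab
}

#' Logistic regression of subtype on covariates
#'
#' Checks whether the subtype label retains any association with the
#' regressed covariates or with disease stage; the stage term is the
#' headline (a well-behaved subtype should not simply encode severity).
#' Categorical levels with fewer than `min_level_n` observations are
#' collapsed into the reference level with a warning.
#'
#' @param data Data frame with `ml_subtype` (two levels) and the covariate
#'   columns.
#' @param covariates Character vector of covariate columns; defaults to
#'   stage, TIV, age, sex, field strength, manufacturer and cohort when
#'   present.
#' @param min_level_n Minimum observations per categorical level, default 3.
#' @return Tibble of coefficients with z statistics and p-values.
#' @export
subtype_covariate_logit <- function(data,
                                    covariates = NULL,
                                    min_level_n = 3) {
  d <- tibble::as_tibble(data)
  if ("subtypable" %in% names(d)) d <- d[d$subtypable, ]
  if (length(unique(d$ml_subtype)) < 2) {
    stop("Subtype outcome is constant; logistic model is degenerate.")
  }
  if (is.null(covariates)) {
    covariates <- intersect(
      c("expected_stage", "tiv_mm3", "age", "sex", "field_strength",
        "manufacturer", "cohort"),
      names(d)
    )
  }
  d$outcome <- as.numeric(d$ml_subtype == max(d$ml_subtype))
  for (v in covariates) {
    if (!is.numeric(d[[v]])) {
      f <- factor(d[[v]])
      tab <- table(f)
      small <- names(tab)[tab < min_level_n]
      if (length(small)) {
        warning("Collapsing sparse level(s) of '", v, "': ",
                paste(small, collapse = ", "))
        ref <- names(tab)[which.max(tab)]
        f <- factor(ifelse(as.character(f) %in% small, ref,
                           as.character(f)))
      }
      if (nlevels(f) < 2) { d[[v]] <- NULL; next }
      d[[v]] <- f
    }
  }
  covariates <- intersect(covariates, names(d))
  fml <- stats::as.formula(paste("outcome ~",
                                 paste(covariates, collapse = " + ")))
  fit <- stats::glm(fml, data = d, family = stats::binomial())
  sm <- summary(fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std_error = sm[, 2], statistic = sm[, 3],
                 p_value = sm[, 4])
}

#' Two-factor ANOVA of stage on syndrome and subtype
#'
#' Additive analysis of variance `stage ~ syndrome + subtype` (no
#' interaction) with Tukey honest-significant-difference pairwise
#' comparisons, for asking whether clinical syndromes sit at different
#' points of a shared trajectory.
#'
#' @param data Data frame with the stage column, `syndrome`, and
#'   `ml_subtype`.
#' @param stage_col Stage column name, default `"expected_stage"`.
#' @return List with `anova` (term-level F table) and `tukey` (pairwise
#'   estimates per factor).
#' @export
stage_anova <- function(data, stage_col = "expected_stage") {
  d <- tibble::as_tibble(data)
  if ("subtypable" %in% names(d)) d <- d[d$subtypable, ]
  d$syndrome <- factor(d$syndrome)
  d$subtype <- factor(d$ml_subtype)
  if (nlevels(d$syndrome) < 2 || nlevels(d$subtype) < 2) {
    stop("Both factors need at least 2 levels.")
  }
  cell_n <- table(d$syndrome, d$subtype)
  if (any(cell_n == 1)) {
    warning("Single-observation cell(s) present; unbalanced least squares used.")
  }
  d$.stage <- d[[stage_col]]
  fit <- stats::aov(.stage ~ syndrome + subtype, data = d)
  sm <- summary(fit)[[1]]
  anova_tab <- tibble::tibble(
    term = trimws(rownames(sm)), df = sm$Df, sum_sq = sm$`Sum Sq`,
    statistic = sm$`F value`, p_value = sm$`Pr(>F)`
  )
  tk <- stats::TukeyHSD(fit)
  tukey <- purrr::map_dfr(names(tk), function(f) {
    m <- tk[[f]]
    tibble::tibble(factor = f, contrast = rownames(m), estimate = m[, 1],
                   conf_low = m[, 2], conf_high = m[, 3],
                   p_adjusted = m[, 4])
  })
  list(anova = anova_tab, tukey = tukey)
}

#' Prorate a partially completed assessment
#'
#' When at least 80\% of an assessment's items are present, the total is
#' prorated as the mean of the completed items times the number expected;
#' otherwise the score is missing.
#'
#' @param items Numeric vector of item scores, `NA` for missing items.
#' @param n_expected Number of items in the full assessment.
#' @param min_complete Minimum completed fraction, default 0.8.
#' @return Adjusted total, or `NA` when too incomplete.
#' @examples
#' prorate_score(c(rep(2, 8), NA, NA), 10)  # 20
#' @export
prorate_score <- function(items, n_expected = length(items),
                          min_complete = 0.8) {
  done <- items[!is.na(items)]
  if (length(done) / n_expected >= min_complete) {
    mean(done) * n_expected
  } else {
    NA_real_
  }
}
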