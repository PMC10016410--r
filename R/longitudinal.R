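#' Build consecutive visit pairs from frozen-model assignments
#'
#' Joins each scan's assignment with the scan calendar and forms one row per
#' consecutive visit pair per subject (a subject with two follow-ups
#' contributes two pairs). Inter-visit time comes from
#' `days_since_baseline`.
#'
#' @param assignments Assignment table from [assign_cohort()] (patient scans;
#'   must carry `subject_id`, `visit`, `days_since_baseline` or be joinable
#'   to `cohort`).
#' @param cohort Optional cohort table supplying `days_since_baseline` and
#'   `syndrome` when absent from `assignments`.
#' @return Tibble of class `visit_pairs`: subject, earlier/later visit and
#'   stage/subtype/subtypable columns, `dt_years`, and syndrome when
#'   available.
#' @export
visit_pairs <- function(assignments, cohort = NULL) {
  a <- tibble::as_tibble(assignments)
  if (!is.null(cohort)) {
    add <- intersect(c("days_since_baseline", "syndrome"),
                     setdiff(names(cohort), names(a)))
    if (length(add)) {
      a <- dplyr::left_join(
        a, cohort[c("subject_id", "visit", add)],
        by = c("subject_id", "visit")
      )
    }
  }
  need <- c("subject_id", "visit", "days_since_baseline", "ml_subtype",
            "ml_stage", "expected_stage", "subtypable")
  miss <- setdiff(need, names(a))
  if (length(miss)) stop("Assignments lack column(s): ",
                         paste(miss, collapse = ", "))
  a <- dplyr::arrange(a, .data$subject_id, .data$visit)
  pairs <- dplyr::group_modify(dplyr::group_by(a, .data$subject_id),
                               function(d, key) {
    if (nrow(d) < 2) return(d[0, 0])
    i <- seq_len(nrow(d) - 1)
    tibble::tibble(
      visit_earlier = d$visit[i], visit_later = d$visit[i + 1],
      dt_years = (d$days_since_baseline[i + 1] -
                    d$days_since_baseline[i]) / 365.25,
      subtype_earlier = d$ml_subtype[i], subtype_later = d$ml_subtype[i + 1],
      stage_earlier = d$ml_stage[i], stage_later = d$ml_stage[i + 1],
      expected_earlier = d$expected_stage[i],
      expected_later = d$expected_stage[i + 1],
      subtypable_earlier = d$subtypable[i],
      subtypable_later = d$subtypable[i + 1],
      syndrome = if ("syndrome" %in% names(d)) d$syndrome[i] else NA_character_
    )
  })
  pairs <- dplyr::ungroup(pairs)
  if (nrow(pairs) > 0 && any(pairs$dt_years <= 0)) {
    stop("Non-positive inter-visit time for subject(s): ",
         paste(unique(pairs$subject_id[pairs$dt_years <= 0]), collapse = ", "))
  }
  class(pairs) <- c("visit_pairs", class(pairs))
  pairs
}

#' Longitudinal subtype stability
#'
#' A pair is consistent when the later scan keeps the earlier scan's subtype,
#' or when the earlier scan was not subtypable at stage 0 (no detectable
#' abnormality) and the later scan has entered a subtype. The transition
#' matrix uses a "normal-appearing" row/column for non-subtypable scans.
#'
#' @param pairs A `visit_pairs` table.
#' @return List with `proportion`, `n_consistent`, `n_total`, and
#'   `transitions` (counts, earlier in rows, later in columns).
#' @export
subtype_stability <- function(pairs) {
  if (nrow(pairs) == 0) stop("No visit pairs.")
  lab <- function(subtypable, subtype) {
    ifelse(subtypable, paste0("subtype_", subtype), "normal_appearing")
  }
  earlier <- lab(pairs$subtypable_earlier, pairs$subtype_earlier)
  later <- lab(pairs$subtypable_later, pairs$subtype_later)
  consistent <- (pairs$subtypable_earlier & pairs$subtypable_later &
                   pairs$subtype_earlier == pairs$subtype_later) |
    (!pairs$subtypable_earlier & pairs$stage_earlier == 0 &
       pairs$subtypable_later)
  levels <- c("normal_appearing",
              paste0("subtype_", sort(unique(c(pairs$subtype_earlier,
                                               pairs$subtype_later)))))
  transitions <- table(factor(earlier, levels), factor(later, levels))
  list(proportion = mean(consistent), n_consistent = sum(consistent),
       n_total = nrow(pairs), transitions = unclass(transitions))
}

#' Longitudinal stage progression
#'
#' Classifies every pair by the maximum-likelihood stage at the later versus
#' earlier scan and reports the proportions that progressed, stayed
#' unchanged, or regressed (summing to 1), overall and within optional
#' grouping columns.
#'
#' @param pairs A `visit_pairs` table.
#' @param by Optional character vector of grouping columns (e.g.
#'   `"subtype_earlier"`, `"syndrome"`).
#' @return Tibble with columns `progressed`, `unchanged`, `regressed`,
#'   `progressed_or_same`, `n_pairs` (one row per group, or a single row).
#' @export
stage_progression <- function(pairs, by = NULL) {
  if (nrow(pairs) == 0) stop("No visit pairs.")
  d <- tibble::as_tibble(pairs)
  d$delta <- sign(d$stage_later - d$stage_earlier)
  if (!is.null(by)) d <- dplyr::group_by(d, dplyr::across(dplyr::all_of(by)))
  dplyr::summarise(
    d,
    progressed = mean(.data$delta > 0),
    unchanged = mean(.data$delta == 0),
    regressed = mean(.data$delta < 0),
    progressed_or_same = mean(.data$delta >= 0),
    n_pairs = dplyr::n(),
    .groups = "drop"
  )
}

#' Per-group stage progression rates
#'
#' Computes each pair's rate as (later minus earlier expected stage) / time,
#' averages within subject and then within group, and compares two named
#' groups with a Welch t-test (95\% confidence interval). The continuous
#' expected stage is used for rates; the discrete maximum-likelihood stage
#' drives [stage_progression()].
#'
#' @param pairs A `visit_pairs` table.
#' @param group Grouping column name (e.g. `"syndrome"`).
#' @param compare Optional length-2 character vector naming the groups to
#'   contrast.
#' @return List with `rates` (per-group tibble) and, when `compare` is
#'   given, `comparison` (Welch t, df, p, 95\% CI).
#' @export
progression_rate <- function(pairs, group = "syndrome", compare = NULL) {
  if (any(pairs$dt_years <= 0)) stop("All pairs need dt_years > 0.")
  d <- tibble::as_tibble(pairs)
  d$rate <- (d$expected_later - d$expected_earlier) / d$dt_years
  per_subject <- dplyr::summarise(
    dplyr::group_by(d, .data$subject_id,
                    grp = .data[[group]]),
    rate = mean(.data$rate), .groups = "drop"
  )
  rates <- dplyr::summarise(
    dplyr::group_by(per_subject, .data$grp),
    mean_rate = mean(.data$rate), sd_rate = stats::sd(.data$rate),
    n = dplyr::n(), .groups = "drop"
  )
  names(rates)[1] <- group
  out <- list(rates = rates)
  if (!is.null(compare)) {
    x <- per_subject$rate[per_subject$grp == compare[1]]
    y <- per_subject$rate[per_subject$grp == compare[2]]
    tt <- stats::t.test(x, y, var.equal = FALSE, conf.level = 0.95)
    out$comparison <- tibble::tibble(
      group_a = compare[1], group_b = compare[2],
      mean_a = mean(x), mean_b = mean(y),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value,
      conf_low = tt$conf.int[1], conf_high = tt$conf.int[2]
    )
  }
  out
}
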