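#' @importFrom tibble tibble as_tibble
NULL

default_roi_table <- function() {
  tibble::tribble(
    ~roi,                ~mean_mm3,
    "midbrain",          6500,
    "pons",              14500,
    "medulla",           4500,
    "scp",               600,
    "dentate",           800,
    "cerebellar_cortex", 100000,
    "vermis",            9000,
    "ventral_dc",        8000,
    "thalamus",          15000,
    "pallidum",          3500,
    "putamen",           9500,
    "caudate",           7500,
    "accumbens",         1000,
    "amygdala",          3300,
    "hippocampus",       7500,
    "insula",            14000,
    "frontal_posterior", 60000,
    "frontal_anterior",  55000,
    "temporal",          110000,
    "parietal",          90000
  )
}

# Default grid: three thresholds for the midbrain (the earliest, most
# dynamic region), two for everything else -> E = 41 events / stages.
# The plateau sits two control SDs past the last event: real end-stage
# atrophy keeps worsening well beyond the last modelled threshold.
default_synth_grid <- function(rois) {
  thr <- stats::setNames(rep(list(c(1, 2)), length(rois)), rois)
  thr[["midbrain"]] <- c(1, 2, 3)
  zmax <- vapply(thr, function(z) max(z) + 2, numeric(1))
  event_grid(thr, z_max = zmax)
}

# Event-label helper: "biomarker.level" strings -> event ids.
sequence_from_labels <- function(labels, grid) {
  ev <- grid$events
  key <- paste(ev$biomarker, ev$level, sep = ".")
  ids <- match(labels, key)
  if (anyNA(ids)) stop("Unknown event label(s): ",
                       paste(labels[is.na(ids)], collapse = ", "))
  validate_sequence(ids, grid)
  ids
}

lv <- function(rois, level) paste(rois, level, sep = ".")

# Two trajectories sharing early brainstem events and diverging in cortical
# involvement: a brainstem-first ("subcortical") and a cortex-early
# ("cortical") ordering.
default_true_sequences <- function(grid) {
  brainstem <- c("midbrain", "pons", "medulla", "scp")
  deep <- c("ventral_dc", "thalamus", "pallidum", "putamen", "dentate")
  late_sub <- c("caudate", "accumbens", "amygdala", "hippocampus",
                "vermis", "cerebellar_cortex")
  cortical <- c("insula", "frontal_posterior", "frontal_anterior",
                "temporal", "parietal")
  subcortical_first <- c(
    lv(brainstem, 1), lv(deep, 1),
    lv(brainstem, 2), lv(deep, 2),
    lv(late_sub, 1), "midbrain.3",
    lv(cortical, 1), lv(late_sub, 2), lv(cortical, 2)
  )
  cortical_first <- c(
    "midbrain.1", "insula.1", "frontal_posterior.1", "thalamus.1",
    "ventral_dc.1", "pallidum.1", "putamen.1", "frontal_anterior.1",
    "midbrain.2", "insula.2", "frontal_posterior.2", "temporal.1",
    "parietal.1", "pons.1", "medulla.1", "scp.1", "dentate.1",
    "thalamus.2", "ventral_dc.2", "pallidum.2", "putamen.2",
    "frontal_anterior.2", "temporal.2", "parietal.2",
    lv(c("caudate", "accumbens", "amygdala", "hippocampus", "vermis",
         "cerebellar_cortex"), 1),
    "midbrain.3", "pons.2", "medulla.2", "scp.2", "dentate.2",
    lv(c("caudate", "accumbens", "amygdala", "hippocampus", "vermis",
         "cerebellar_cortex"), 2)
  )
  list(sequence_from_labels(subcortical_first, grid),
       sequence_from_labels(cortical_first, grid))
}

default_covariate_effects <- function(roi_tab) {
  tibble::tibble(
    roi = roi_tab$roi,
    age = -0.004 * roi_tab$mean_mm3,          # mm3 per year
    sex_male = 0.01 * roi_tab$mean_mm3,       # offset, M vs F
    tiv = 0.6 * roi_tab$mean_mm3 / 1.4e6,     # mm3 per mm3 TIV
    field_3t = 0.005 * roi_tab$mean_mm3,      # 3 T vs 1.5 T
    manu_ge = -0.003 * roi_tab$mean_mm3,      # vs Siemens
    manu_philips = 0.002 * roi_tab$mean_mm3
  )
}

default_score_models <- function() {
  tibble::tribble(
    ~score,            ~intercept, ~stage_slope, ~subtype_offset, ~noise_sd, ~min, ~max,
    "psprs_total",     18,    1.00,  -7.0,  9.0,  0, 100,
    "psprs_history",    4,    0.22,  -1.5,  2.6,  0, 24,
    "psprs_mentation",  2,    0.08,   0.0,  1.8,  0, 16,
    "psprs_bulbar",     1.2,  0.07,  -0.5,  1.4,  0, 8,
    "psprs_ocular",     4,    0.22,  -2.0,  2.8,  0, 16,
    "psprs_limb",       3,    0.08,   0.0,  2.2,  0, 16,
    "psprs_gait",       5,    0.25,  -1.8,  3.6,  0, 20,
    "updrs",           15,    0.75,  -7.0, 12.0,  0, 199,
    "seadl",           75,   -1.10,   3.0, 15.0,  0, 100,
    "mmse",            27,   -0.07,  -0.5,  3.0,  0, 30
  )
}

#' Configuration for the synthetic atrophy cohort
#'
#' Defines every distribution the generator draws from. The defaults mirror
#' the study conditions the package is designed around: 290 controls and 426
#' patients over 20 selected grey-matter regions (41 z-score events), two
#' latent subtypes with fractions 0.75/0.25 whose trajectories share early
#' brainstem events and diverge in cortical involvement, clinical syndromes
#' enriched about 81--82\% for the matching subtype, follow-up scans
#' 0.91 +/- 0.38 years apart with syndrome-dependent progression rates of
#' about 1.86 (Richardson) versus 0.66 (subcortical-variant) stages/year,
#' and clinical scores that worsen with stage and differ by subtype.
#'
#' @param n_controls,n_patients Cohort sizes.
#' @param roi_table Tibble with `roi` and `mean_mm3` columns; SDs default to
#'   8\% of the mean.
#' @param roi_baseline_sd Optional named vector of per-region SDs (mm^3).
#' @param covariate_effects Tibble of per-region linear coefficients (see
#'   the default for the column set).
#' @param event_grid Event grid defining the z-score trajectories.
#' @param true_sequences List of event sequences, one per latent subtype.
#' @param true_fractions Subtype mixing fractions (sum to 1).
#' @param noise_sd Total observation noise on the z-score scale, default 1.
#'   Decomposed into a persistent per-subject effect and an independent
#'   per-scan component (see `scan_noise_sd`); the marginal noise at any
#'   single scan has SD `noise_sd`.
#' @param scan_noise_sd Scan-level (rescan) component of the noise, default
#'   0.3 z-units, matching the high scan-rescan reliability of automated
#'   volumetry; the remainder, `sqrt(noise_sd^2 - scan_noise_sd^2)`, is a
#'   subject-level effect shared by all of a subject's visits.
#' @param stage_distribution Probabilities over true baseline stages 0..E;
#'   default uniform.
#' @param syndromes Character vector of syndrome labels.
#' @param syndrome_enrichment Matrix of P(syndrome | subtype); rows =
#'   subtypes, columns = syndromes, rows summing to 1.
#' @param followup_spec List: `gap_mean`, `gap_sd` (years), `p_followup`
#'   (probability ladder for 1st, 2nd, ... follow-up), `rates` (named
#'   stages/year per syndrome), `stage_noise_lambda` (Poisson mean of the
#'   non-negative integer stage jitter).
#' @param score_models Tibble of per-score linear models (intercept, stage
#'   slope, subtype offset for subtype 2, noise SD, clipping range).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_controls = 290,
                         n_patients = 426,
                         roi_table = default_roi_table(),
                         roi_baseline_sd = NULL,
                         covariate_effects = NULL,
                         event_grid = NULL,
                         true_sequences = NULL,
                         true_fractions = c(0.75, 0.25),
                         noise_sd = 1,
                         scan_noise_sd = 0.3,
                         stage_distribution = NULL,
                         syndromes = c("RS", "cortical", "subcortical"),
                         syndrome_enrichment = NULL,
                         followup_spec = NULL,
                         score_models = default_score_models()) {
  if (any(roi_table$mean_mm3 <= 0)) stop("Baseline means must be positive.")
  rois <- roi_table$roi
  if (is.null(roi_baseline_sd)) {
    roi_baseline_sd <- stats::setNames(0.08 * roi_table$mean_mm3, rois)
  }
  if (any(roi_baseline_sd <= 0)) stop("`roi_baseline_sd` must be positive.")
  if (is.null(covariate_effects)) covariate_effects <- default_covariate_effects(roi_table)
  if (is.null(event_grid)) event_grid <- default_synth_grid(rois)
  if (!setequal(event_grid$biomarkers, rois)) {
    stop("Event grid biomarkers must match `roi_table$roi`.")
  }
  if (is.null(true_sequences)) true_sequences <- default_true_sequences(event_grid)
  for (s in true_sequences) validate_sequence(s, event_grid)
  if (abs(sum(true_fractions) - 1) > 1e-12 || any(true_fractions <= 0)) {
    stop("`true_fractions` must be positive and sum to 1 (within 1e-12).")
  }
  if (length(true_fractions) != length(true_sequences)) {
    stop("One fraction per true sequence required.")
  }
  E <- event_grid$n_events
  if (is.null(stage_distribution)) {
    # discretised truncated normal centred mid-trajectory (mean 0.45 E,
    # SD 0.25 E): at E = 41 this gives mean ~18.5, SD ~10, the shape of
    # observed baseline stage distributions in symptomatic cohorts
    w <- stats::dnorm(0:E, mean = 0.45 * E, sd = 0.25 * E)
    stage_distribution <- w / sum(w)
  }
  if (length(stage_distribution) != E + 1 ||
      abs(sum(stage_distribution) - 1) > 1e-8) {
    stop("`stage_distribution` must have E + 1 probabilities summing to 1.")
  }
  if (is.null(syndrome_enrichment)) {
    stopifnot(identical(syndromes, c("RS", "cortical", "subcortical")),
              length(true_sequences) == 2)
    syndrome_enrichment <- rbind(c(0.77, 0.19, 0.04),
                                 c(0.16, 0.82, 0.02))
  }
  syndrome_enrichment <- as.matrix(syndrome_enrichment)
  if (nrow(syndrome_enrichment) != length(true_sequences) ||
      ncol(syndrome_enrichment) != length(syndromes) ||
      any(abs(rowSums(syndrome_enrichment) - 1) > 1e-8)) {
    stop("`syndrome_enrichment` rows must be P(syndrome | subtype) summing to 1.")
  }
  dimnames(syndrome_enrichment) <- list(NULL, syndromes)
  if (is.null(followup_spec)) {
    followup_spec <- list(
      gap_mean = 0.91, gap_sd = 0.38,
      p_followup = c(0.86, 0.22, 0.02),
      rates = c(RS = 1.86, cortical = 1.60, subcortical = 0.66),
      stage_noise_lambda = 0.5
    )
  }
  if (any(followup_spec$rates < 0)) stop("Progression rates must be >= 0.")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.")
  scan_noise_sd <- min(scan_noise_sd, noise_sd)

  structure(
    list(n_controls = n_controls, n_patients = n_patients,
         roi_table = roi_table, roi_baseline_sd = roi_baseline_sd,
         covariate_effects = covariate_effects, event_grid = event_grid,
         true_sequences = true_sequences, true_fractions = true_fractions,
         noise_sd = noise_sd, scan_noise_sd = scan_noise_sd,
         subject_noise_sd = sqrt(noise_sd^2 - scan_noise_sd^2),
         stage_distribution = stage_distribution,
         syndromes = syndromes, syndrome_enrichment = syndrome_enrichment,
         followup_spec = followup_spec, score_models = score_models),
    class = "synth_config"
  )
}

# Reference covariate profile the baseline means refer to: 65-year-old
# female, TIV 1.4e6 mm3, 1.5 T Siemens.
covariate_shift <- function(config, cov) {
  fx <- config$covariate_effects
  shift <- outer(cov$age - 65, fx$age) +
    outer(as.numeric(cov$sex == "M"), fx$sex_male) +
    outer(cov$tiv_mm3 - 1.4e6, fx$tiv) +
    outer(as.numeric(cov$field_strength == 3), fx$field_3t) +
    outer(as.numeric(cov$manufacturer == "GE"), fx$manu_ge) +
    outer(as.numeric(cov$manufacturer == "Philips"), fx$manu_philips)
  colnames(shift) <- fx$roi
  shift
}

draw_covariates <- function(n, age_mean, age_sd) {
  tibble::tibble(
    age = pmax(40, stats::rnorm(n, age_mean, age_sd)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    tiv_mm3 = stats::rnorm(n, 1.4e6, 1.3e5),
    field_strength = sample(c(1.5, 3), n, replace = TRUE, prob = c(0.4, 0.6)),
    manufacturer = sample(c("Siemens", "GE", "Philips"), n, replace = TRUE,
                          prob = c(0.5, 0.3, 0.2)),
    cohort = sample(paste0("cohort_", 1:3), n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
  )
}

# z matrix -> volume matrix: baseline + covariate shift - z * baseline_sd,
# clipped at 1 mm3 (a warning reports any clipping).
volumes_from_z <- function(Z, config, cov) {
  rois <- config$roi_table$roi
  V <- matrix(rep(config$roi_table$mean_mm3, each = nrow(Z)),
              nrow = nrow(Z), dimnames = list(NULL, rois))
  V <- V + covariate_shift(config, cov) -
    sweep(Z[, rois, drop = FALSE], 2, config$roi_baseline_sd[rois], "*")
  n_clip <- sum(V < 1)
  if (n_clip > 0) {
    warning(n_clip, " volume(s) clipped at 1 mm3.")
    V[V < 1] <- 1
  }
  V
}

#' Generate the baseline synthetic cohort
#'
#' Controls draw each region's z-score from a standard normal; patients draw
#' a latent subtype and baseline stage, take the subtype trajectory's
#' expected z at that stage and add Gaussian noise with total SD `noise_sd`,
#' split into a persistent subject effect (returned in `subject_effects`,
#' reused by [simulate_followups()]) and an independent scan component.
#' Volumes invert the z-scoring construction: `volume = baseline +
#' covariate effects - z * baseline_sd`, so the raw mm^3 tables can be
#' pushed through the real preprocessing path. Identical seeds give
#' byte-identical output.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return List with `cohort` (one row per scan, standard schema), `truth`
#'   (subject_id, visit, true_subtype, true_stage, rate) and
#'   `subject_effects` (patients x regions matrix of latent z offsets).
#' @export
simulate_baseline <- function(config, seed = 1) {
  withr::local_seed(seed)
  rois <- config$roi_table$roi
  E <- config$event_grid$n_events

  ctrl_cov <- draw_covariates(config$n_controls, 62.5, 9.4)
  pat_cov <- draw_covariates(config$n_patients, 68.5, 6.8)

  Zc <- matrix(stats::rnorm(config$n_controls * length(rois)),
               nrow = config$n_controls, dimnames = list(NULL, rois))

  subtype <- sample.int(length(config$true_fractions), config$n_patients,
                        replace = TRUE, prob = config$true_fractions)
  stage <- sample(0:E, config$n_patients, replace = TRUE,
                  prob = config$stage_distribution)
  G <- lapply(config$true_sequences, traj_matrix, grid = config$event_grid)
  subject_effects <- matrix(
    stats::rnorm(config$n_patients * length(rois),
                 sd = config$subject_noise_sd),
    nrow = config$n_patients, dimnames = list(NULL, rois)
  )
  Zp <- t(vapply(seq_len(config$n_patients), function(j) {
    G[[subtype[j]]][rois, stage[j] + 1L]
  }, numeric(length(rois))))
  Zp <- Zp + subject_effects +
    matrix(stats::rnorm(length(Zp), sd = config$scan_noise_sd),
           nrow = nrow(Zp))
  colnames(Zp) <- rois

  mk <- function(ids, cov, grp, V) {
    syn <- if (grp == "control") "control" else "unknown"
    dplyr::bind_cols(
      tibble::tibble(subject_id = ids, visit = 0L, days_since_baseline = 0,
                     group = grp, syndrome = syn),
      cov,
      tibble::as_tibble(V)
    )
  }
  Vc <- volumes_from_z(Zc, config, ctrl_cov)
  Vp <- volumes_from_z(Zp, config, pat_cov)
  colnames(Vc) <- colnames(Vp) <- paste0("roi_", rois)
  ctrl_ids <- sprintf("ctrl_%04d", seq_len(config$n_controls))
  pat_ids <- sprintf("pat_%04d", seq_len(config$n_patients))
  cohort <- dplyr::bind_rows(
    mk(ctrl_ids, ctrl_cov, "control", Vc),
    mk(pat_ids, pat_cov, "patient", Vp)
  )
  truth <- tibble::tibble(
    subject_id = pat_ids, visit = 0L,
    true_subtype = subtype, true_stage = stage, rate = NA_real_
  )
  rownames(subject_effects) <- pat_ids
  list(cohort = cohort, truth = truth, subject_effects = subject_effects)
}

#' Attach syndrome labels and clinical scores
#'
#' Samples each patient's clinical syndrome from P(syndrome | true subtype)
#' and computes every clinical score as
#' `intercept + stage_slope * true_stage + subtype_offset * (subtype == 2) +
#' noise`, clipped to the score's published range. Syndromes are sampled per
#' subject (stable across visits); scores are computed per scan so they
#' track stage at follow-up. Controls keep syndrome `"control"` and missing
#' scores.
#'
#' @param cohort,truth As returned by [simulate_baseline()] (optionally
#'   after [simulate_followups()]).
#' @param config The [synth_config()].
#' @param seed Integer seed.
#' @return List with updated `cohort` and `truth`.
#' @export
attach_syndromes_and_scores <- function(cohort, truth, config, seed = 1) {
  withr::local_seed(seed)
  subjects <- truth[truth$visit == 0, c("subject_id", "true_subtype")]
  subjects <- subjects[order(subjects$subject_id), ]
  syn <- vapply(subjects$true_subtype, function(s) {
    sample(config$syndromes, 1, prob = config$syndrome_enrichment[s, ])
  }, character(1))
  syn_map <- stats::setNames(syn, subjects$subject_id)

  cohort$syndrome <- ifelse(cohort$group == "patient",
                            unname(syn_map[cohort$subject_id]),
                            cohort$syndrome)
  key <- paste(truth$subject_id, truth$visit)
  idx <- match(paste(cohort$subject_id, cohort$visit), key)
  stage <- truth$true_stage[idx]
  subtype <- truth$true_subtype[idx]

  for (r in seq_len(nrow(config$score_models))) {
    m <- config$score_models[r, ]
    val <- m$intercept + m$stage_slope * stage +
      m$subtype_offset * as.numeric(subtype == 2) +
      stats::rnorm(nrow(cohort), 0, m$noise_sd)
    cohort[[m$score]] <- ifelse(is.na(stage), NA_real_,
                                pmin(pmax(val, m$min), m$max))
  }
  list(cohort = cohort, truth = truth)
}

#' Simulate follow-up scans
#'
#' Each patient receives follow-up visits according to the configured
#' probability ladder. Inter-visit gaps are Gaussian (`gap_mean`,
#' `gap_sd`), truncated to be positive. The true stage advances by
#' `round(rate * gap)` plus a non-negative Poisson jitter, never decreases,
#' and is capped at the end stage E; the subtype never changes. Rates are
#' looked up per syndrome, so syndromes must be attached first. Volumes at
#' follow-up are regenerated from the advanced stage through the same
#' z-to-volume construction; age advances with the gap, scanner covariates
#' stay fixed.
#'
#' @inheritParams attach_syndromes_and_scores
#' @param seed Integer seed.
#' @param subject_effects Latent per-subject z offsets from
#'   [simulate_baseline()]; when `NULL`, follow-up noise is drawn
#'   independently at the full `noise_sd` (visits then decorrelate).
#' @return List with `cohort` (baseline plus follow-up rows) and `truth`
#'   (one row per patient scan, `rate` filled in).
#' @export
simulate_followups <- function(cohort, truth, config, seed = 1,
                               subject_effects = NULL) {
  withr::local_seed(seed)
  fs <- config$followup_spec
  if (any(fs$rates < 0)) stop("Progression rates must be >= 0.")
  E <- config$event_grid$n_events
  rois <- config$roi_table$roi
  G <- lapply(config$true_sequences, traj_matrix, grid = config$event_grid)

  base <- cohort[cohort$group == "patient" & cohort$visit == 0, ]
  if (any(base$syndrome == "unknown")) {
    stop("Attach syndromes before simulating follow-ups (rates are per syndrome).")
  }
  bt <- truth[truth$visit == 0, ]
  new_rows <- list()
  new_truth <- list()
  truth$rate <- unname(fs$rates[base$syndrome[match(truth$subject_id,
                                                    base$subject_id)]])

  for (i in seq_len(nrow(base))) {
    n_fu <- 0L
    for (p in fs$p_followup) {
      if (stats::runif(1) < p) n_fu <- n_fu + 1L else break
    }
    if (n_fu == 0L) next
    sid <- base$subject_id[i]
    rate <- unname(fs$rates[[base$syndrome[i]]])
    stage <- bt$true_stage[bt$subject_id == sid]
    subtype <- bt$true_subtype[bt$subject_id == sid]
    days <- 0
    for (v in seq_len(n_fu)) {
      gap <- 0
      while (gap <= 0) gap <- stats::rnorm(1, fs$gap_mean, fs$gap_sd)
      days <- days + gap * 365.25
      stage <- min(E, stage + round(rate * gap) +
                     stats::rpois(1, fs$stage_noise_lambda))
      z <- G[[subtype]][rois, stage + 1L] +
        (if (is.null(subject_effects)) {
          stats::rnorm(length(rois), 0, config$noise_sd)
        } else {
          subject_effects[sid, rois] +
            stats::rnorm(length(rois), 0, config$scan_noise_sd)
        })
      cov <- base[i, c("age", "sex", "tiv_mm3", "field_strength",
                       "manufacturer", "cohort")]
      cov$age <- cov$age + days / 365.25
      V <- volumes_from_z(matrix(z, nrow = 1, dimnames = list(NULL, rois)),
                          config, cov)
      colnames(V) <- paste0("roi_", rois)
      row <- dplyr::bind_cols(
        tibble::tibble(subject_id = sid, visit = v,
                       days_since_baseline = days, group = "patient",
                       syndrome = base$syndrome[i]),
        cov, tibble::as_tibble(V)
      )
      new_rows[[length(new_rows) + 1L]] <- row
      new_truth[[length(new_truth) + 1L]] <- tibble::tibble(
        subject_id = sid, visit = v, true_subtype = subtype,
        true_stage = stage, rate = rate
      )
    }
  }
  cohort_out <- dplyr::bind_rows(cohort, dplyr::bind_rows(new_rows))
  truth_out <- dplyr::bind_rows(truth, dplyr::bind_rows(new_truth))
  truth_out <- dplyr::arrange(truth_out, .data$subject_id, .data$visit)
  list(cohort = cohort_out, truth = truth_out)
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_baseline()],
#' [attach_syndromes_and_scores()], [simulate_followups()], and a final
#' score pass over the follow-up scans. Deterministic given `seed`.
#'
#' @param config A [synth_config()]; defaults to the package's standard
#'   study conditions.
#' @param seed Integer seed.
#' @return List with `cohort` and `truth` tibbles.
#' @export
simulate_cohort <- function(config = synth_config(), seed = 1) {
  b0 <- simulate_baseline(config, seed = seed)
  b <- attach_syndromes_and_scores(b0$cohort, b0$truth, config,
                                   seed = seed + 1)
  f <- simulate_followups(b$cohort, b$truth, config, seed = seed + 2,
                          subject_effects = b0$subject_effects)
  attach_syndromes_and_scores(f$cohort, f$truth, config, seed = seed + 1)
}

#' Simulate a bare z-score panel from a known model
#'
#' Draws scans directly on the z-score scale from given true sequences and
#' fractions (stages uniform over 0..E), bypassing the volume/covariate
#' layer. Used for focused recovery experiments on the model core.
#'
#' @param grid An `event_grid`.
#' @param sequences List of true event sequences.
#' @param n Number of scans.
#' @param fractions Subtype fractions, default uniform.
#' @param noise_sd Observation noise SD, default 1.
#' @param seed Integer seed.
#' @return List with `z` (matrix), `subtype`, `stage`.
#' @export
simulate_zscores <- function(grid, sequences, n, fractions = NULL,
                             noise_sd = 1, seed = 1) {
  withr::local_seed(seed)
  C <- length(sequences)
  if (is.null(fractions)) fractions <- rep(1 / C, C)
  E <- grid$n_events
  subtype <- sample.int(C, n, replace = TRUE, prob = fractions)
  stage <- sample(0:E, n, replace = TRUE)
  G <- lapply(sequences, traj_matrix, grid = grid)
  Z <- t(vapply(seq_len(n), function(j) G[[subtype[j]]][, stage[j] + 1L],
                numeric(length(grid$biomarkers))))
  Z <- Z + matrix(stats::rnorm(length(Z), sd = noise_sd), nrow = n)
  colnames(Z) <- grid$biomarkers
  list(z = Z, subtype = subtype, stage = stage)
}
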