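#' @importFrom rlang .data
NULL

roi_columns <- function(data, prefix = "roi_") {
  grep(paste0("^", prefix), names(data), value = TRUE)
}

#' Combine left/right hemisphere volumes
#'
#' Sums paired left/right regional volumes (columns suffixed `_L` / `_R`)
#' into a single combined column; midline (unpaired) regions pass through
#' unchanged. A left label whose right partner is absent (or vice versa) is
#' an error naming the orphan, since silently dropping half a structure
#' would bias the volume.
#'
#' @param data A cohort data frame whose regional volume columns start with
#'   `prefix`.
#' @param prefix Volume column prefix, default `"roi_"`.
#' @return The data frame with each `_L`/`_R` pair replaced by their sum.
#' @examples
#' d <- tibble::tibble(roi_thal_L = 5000, roi_thal_R = 5200, roi_pons = 14000)
#' combine_hemispheres(d)
#' @export
combine_hemispheres <- function(data, prefix = "roi_") {
  rois <- roi_columns(data, prefix)
  lefts <- rois[grepl("_L$", rois)]
  rights <- rois[grepl("_R$", rois)]
  stems_l <- sub("_L$", "", lefts)
  stems_r <- sub("_R$", "", rights)
  orphan_l <- setdiff(stems_l, stems_r)
  orphan_r <- setdiff(stems_r, stems_l)
  orphans <- c(if (length(orphan_l)) paste0(orphan_l, "_R"),
               if (length(orphan_r)) paste0(orphan_r, "_L"))
  if (length(orphans)) {
    stop("Hemisphere label(s) without a partner: ",
         paste(orphans, collapse = ", "))
  }
  out <- data
  for (stem in stems_l) {
    out[[stem]] <- out[[paste0(stem, "_L")]] + out[[paste0(stem, "_R")]]
  }
  out[c(paste0(stems_l, "_L"), paste0(stems_l, "_R"))] <- NULL
  out
}

# Build the covariate design matrix used by the adjuster. Categorical
# covariates are treatment-coded with the most frequent *control* level as
# reference; covariates with a single observed level are dropped with a
# warning.
adjuster_design <- function(data, spec) {
  df <- data.frame(row.names = seq_len(nrow(data)))
  for (v in spec$numeric) df[[v]] <- as.numeric(data[[v]])
  for (v in names(spec$levels)) {
    lev <- spec$levels[[v]]
    val <- as.character(data[[v]])
    unseen <- setdiff(unique(val), lev)
    if (length(unseen)) {
      warning("Unseen level(s) in '", v, "' (", paste(unseen, collapse = ", "),
              ") mapped to reference level '", lev[1], "'.")
      val[val %in% unseen] <- lev[1]
    }
    df[[v]] <- factor(val, levels = lev)
  }
  stats::model.matrix(~ ., data = df)
}

#' Fit a control-referenced covariate adjuster
#'
#' Fits, on the control scans only, one ordinary-least-squares model per
#' region: volume ~ age + sex + TIV + field strength + manufacturer. The
#' model is later propagated to the patients by [apply_adjuster()], so the
#' adjustment is anchored in the healthy population rather than being
#' contaminated by disease-related atrophy. The controls' adjusted-volume
#' mean and SD per region are stored for z-scoring.
#'
#' @param data Cohort data frame; rows with `group == "control"` are used.
#' @param covariates Named list with `numeric` and `categorical` character
#'   vectors of column names. Defaults to the standard cohort schema
#'   (`age`, `tiv_mm3`; `sex`, `field_strength`, `manufacturer`).
#' @param prefix Volume column prefix.
#' @return A `covariate_adjuster` object.
#' @export
fit_covariate_adjuster <- function(data,
                                   covariates = list(
                                     numeric = c("age", "tiv_mm3"),
                                     categorical = c("sex", "field_strength",
                                                     "manufacturer")),
                                   prefix = "roi_") {
  controls <- data[data$group == "control", , drop = FALSE]
  rois <- roi_columns(data, prefix)
  if (length(rois) == 0) stop("No volume columns with prefix '", prefix, "'.")

  levels_kept <- list()
  for (v in covariates$categorical) {
    tab <- sort(table(as.character(controls[[v]])), decreasing = TRUE)
    if (length(tab) < 2) {
      warning("Covariate '", v, "' has a single level in controls; dropped.")
      next
    }
    levels_kept[[v]] <- names(tab)  # most frequent control level = reference
  }
  spec <- list(numeric = covariates$numeric, levels = levels_kept)

  M <- adjuster_design(controls, spec)
  if (nrow(M) < ncol(M) + 2) {
    stop("Too few controls (", nrow(M), ") for ", ncol(M),
         " regression coefficients.")
  }
  if (qr(M)$rank < ncol(M)) stop("Covariate design is rank deficient.")

  Y <- as.matrix(controls[rois])
  fit <- stats::lm.fit(M, Y)
  coefs <- fit$coefficients                      # p x I
  pred <- M %*% coefs
  pred_mean <- colMeans(pred)                    # control-mean prediction
  adj <- Y - sweep(pred, 2, pred_mean)           # residual + control mean
  ctrl_mean <- colMeans(adj)
  ctrl_sd <- apply(adj, 2, stats::sd)
  if (any(ctrl_sd <= 0)) {
    stop("Zero control SD for: ",
         paste(rois[ctrl_sd <= 0], collapse = ", "))
  }

  structure(
    list(coefs = coefs, spec = spec, pred_mean = pred_mean, rois = rois,
         prefix = prefix, control_mean = ctrl_mean, control_sd = ctrl_sd,
         n_controls = nrow(M)),
    class = "covariate_adjuster"
  )
}

#' @export
print.covariate_adjuster <- function(x, ...) {
  cat("<covariate_adjuster> ", length(x$rois), " regions, fitted on ",
      x$n_controls, " controls\n", sep = "")
  invisible(x)
}

#' Apply a fitted covariate adjuster
#'
#' Replaces each regional volume by its covariate-adjusted value,
#' `observed - (predicted - control-mean prediction)`, i.e. the residual
#' shifted back to the control reference so volumes keep their mm^3 scale.
#' Applied identically to controls and patients (and to follow-up scans,
#' with no refit). Unseen categorical levels map to the reference level
#' with a warning. Adjustment is not idempotent: re-applying it to already
#' adjusted volumes would regress out the covariates a second time.
#'
#' @param adjuster A `covariate_adjuster`.
#' @param data Cohort data frame carrying the covariates the adjuster was
#'   fit with.
#' @return `data` with volume columns replaced by adjusted volumes.
#' @export
apply_adjuster <- function(adjuster, data) {
  M <- adjuster_design(data, adjuster$spec)
  pred <- M %*% adjuster$coefs
  out <- data
  out[adjuster$rois] <- as.data.frame(
    as.matrix(data[adjuster$rois]) - sweep(pred, 2, adjuster$pred_mean)
  )
  tibble::as_tibble(out)
}

#' Cohen's d effect size
#'
#' Standardised mean difference `(mean_a - mean_b) / pooled SD` with the
#' pooled standard deviation
#' `sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`. In the
#' biomarker-selection step the first group is the controls and the second
#' the patients, on covariate-adjusted volumes, so atrophy gives d > 0.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return Scalar effect size.
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))  # -2
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("Each group needs at least 2 values.")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("Pooled variance is zero; effect size undefined.")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Select biomarkers by control-versus-patient effect size
#'
#' Computes Cohen's d (controls minus patients, so regions that atrophy in
#' disease score positive) on covariate-adjusted baseline volumes and keeps
#' regions with `d >= threshold`, ordered by descending d.
#'
#' @param data Adjusted cohort data frame; only baseline scans
#'   (`visit == 0`) enter the comparison.
#' @param threshold Minimum effect size, default 0.6 (moderate-to-large).
#' @param prefix Volume column prefix.
#' @return A tibble of class `biomarker_selection` with columns `roi`
#'   (without prefix), `d` and `selected`, sorted by descending `d`.
#' @export
select_biomarkers <- function(data, threshold = 0.6, prefix = "roi_") {
  base <- data[data$visit == 0, , drop = FALSE]
  rois <- roi_columns(base, prefix)
  ctrl <- base[base$group == "control", , drop = FALSE]
  pat <- base[base$group == "patient", , drop = FALSE]
  if (nrow(ctrl) < 2 || nrow(pat) < 2) {
    stop("Need both controls and patients at baseline.")
  }
  d <- vapply(rois, function(r) cohens_d(ctrl[[r]], pat[[r]]), numeric(1))
  tab <- tibble::tibble(
    roi = sub(paste0("^", prefix), "", rois),
    d = unname(d),
    selected = unname(d) >= threshold
  )
  tab <- dplyr::arrange(tab, dplyr::desc(.data$d))
  if (!any(tab$selected)) {
    stop("No region reaches d >= ", threshold,
         "; review the effect-size threshold.")
  }
  class(tab) <- c("biomarker_selection", class(tab))
  tab
}

#' Selected biomarker names
#' @param selection A `biomarker_selection` table.
#' @return Character vector of selected region names (descending d).
#' @export
selected_biomarkers <- function(selection) {
  selection$roi[selection$selected]
}

#' Compute the sign-flipped z-score panel
#'
#' Converts covariate-adjusted volumes into z-scores relative to the control
#' distribution, `x = -(v_adj - mu_control) / sd_control`: subtracting the
#' control mean, dividing by the control SD, and flipping the sign so that
#' larger x means more atrophy. The panel covers every scan passed in
#' (controls, patients, and follow-ups, which reuse the baseline-fit
#' statistics). Scans missing any selected region are excluded with a
#' message.
#'
#' @param data Adjusted cohort data frame (output of [apply_adjuster()]).
#' @param adjuster The `covariate_adjuster` providing control mean/SD.
#' @param biomarkers Character vector of selected region names (without
#'   prefix), e.g. from [selected_biomarkers()].
#' @return A `zscore_panel`: list with `scans` (scan metadata tibble), `z`
#'   (scans x biomarkers matrix) and `biomarkers`.
#' @export
compute_zscores <- function(data, adjuster, biomarkers) {
  cols <- paste0(adjuster$prefix, biomarkers)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("Data lacks selected regions: ", paste(missing_cols, collapse = ", "))
  }
  mu <- adjuster$control_mean[cols]
  sd <- adjuster$control_sd[cols]
  if (any(sd <= 0)) stop("Control SD is zero for a selected region.")

  V <- as.matrix(data[cols])
  keep <- stats::complete.cases(V)
  if (any(!keep)) {
    message(sum(!keep), " scan(s) excluded: missing a selected region volume.")
  }
  Z <- -sweep(sweep(V[keep, , drop = FALSE], 2, mu), 2, sd, "/")
  colnames(Z) <- biomarkers

  meta_cols <- intersect(
    c("subject_id", "visit", "days_since_baseline", "group", "syndrome",
      "age", "sex", "tiv_mm3", "field_strength", "manufacturer", "cohort"),
    names(data)
  )
  scans <- tibble::as_tibble(data[keep, meta_cols, drop = FALSE])
  if (!"scan_id" %in% names(scans)) {
    scans$scan_id <- if (all(c("subject_id", "visit") %in% names(scans))) {
      paste(scans$subject_id, scans$visit, sep = "_v")
    } else {
      sprintf("scan_%04d", seq_len(nrow(scans)))
    }
  }
  structure(
    list(scans = scans, z = Z, biomarkers = biomarkers),
    class = "zscore_panel"
  )
}

#' @export
print.zscore_panel <- function(x, ...) {
  cat("<zscore_panel> ", nrow(x$z), " scans x ", ncol(x$z),
      " biomarkers\n", sep = "")
  invisible(x)
}

#' Extract the z-score matrix from a panel
#'
#' @param panel A `zscore_panel`.
#' @param scans Which scans: `"all"`, `"patient_baseline"` (the model-fitting
#'   set), `"patient"`, or `"control"`.
#' @return Numeric matrix (scans x biomarkers).
#' @export
panel_matrix <- function(panel, scans = c("all", "patient_baseline",
                                          "patient", "control")) {
  scans <- match.arg(scans)
  keep <- switch(scans,
    all = rep(TRUE, nrow(panel$z)),
    patient_baseline = panel$scans$group == "patient" & panel$scans$visit == 0,
    patient = panel$scans$group == "patient",
    control = panel$scans$group == "control"
  )
  panel$z[keep, , drop = FALSE]
}

#' @export
as_tibble.zscore_panel <- function(x, ...) {
  dplyr::bind_cols(x$scans, tibble::as_tibble(x$z))
}

#' Run the full biomarker preparation pipeline
#'
#' Fixed pipeline order: combine hemispheres (if any paired labels), fit the
#' covariate adjuster on controls, adjust all scans, select biomarkers by
#' effect size on baseline scans, and z-score every scan against the
#' adjusted control distribution.
#'
#' @param data Raw cohort data frame (standard schema).
#' @param d_threshold Effect-size selection threshold, default 0.6.
#' @param prefix Volume column prefix.
#' @return List with `adjuster`, `selection`, `panel` and the adjusted data.
#' @export
prepare_biomarkers <- function(data, d_threshold = 0.6, prefix = "roi_") {
  data <- combine_hemispheres(data, prefix)
  adjuster <- fit_covariate_adjuster(data, prefix = prefix)
  adjusted <- apply_adjuster(adjuster, data)
  selection <- select_biomarkers(adjusted, threshold = d_threshold,
                                 prefix = prefix)
  panel <- compute_zscores(adjusted, adjuster, selected_biomarkers(selection))
  list(adjuster = adjuster, selection = selection, panel = panel,
       adjusted = adjusted)
}
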