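#' Write and read the cohort CSV schema
#'
#' The cohort file has one row per scan with identifier, group, syndrome,
#' covariate, regional volume (`roi_*`) and clinical score columns; the
#' truth file (synthetic cohorts only) has one row per patient scan with
#' the latent subtype, stage and progression rate.
#'
#' @param cohort,truth Tibbles as produced by [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns the file paths invisibly;
#'   `read_cohort()` returns a list with `cohort` and (if present) `truth`.
#' @export
write_cohort <- function(cohort, truth = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "cohort.csv")
  readr::write_csv(cohort, paths)
  if (!is.null(truth)) {
    truth_path <- file.path(dir, "truth.csv")
    readr::write_csv(truth, truth_path)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir = ".") {
  cohort <- readr::read_csv(file.path(dir, "cohort.csv"),
                            show_col_types = FALSE)
  out <- list(cohort = cohort)
  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path)) {
    out$truth <- readr::read_csv(truth_path, show_col_types = FALSE)
  }
  out
}

#' Serialise a fitted model to JSON
#'
#' Stores the event grid, per-subtype sequences (as event labels), mixture
#' fractions, log-likelihood and seed record in a plain JSON document that
#' [read_sustain_model()] restores.
#'
#' @param fit A `sustain_fit`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_sustain_model <- function(fit, path) {
  grid <- fit$grid
  thr <- split(grid$events$z, grid$events$biomarker)[grid$biomarkers]
  doc <- list(
    grid = list(thresholds = thr,
                z_max = as.list(grid$z_max),
                sigma = as.list(grid$sigma)),
    sequences = lapply(fit$sequences, function(s) event_labels(grid)[s]),
    sequence_event_ids = fit$sequences,
    fractions = fit$fractions,
    loglik = fit$loglik,
    seed = fit$seed
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sustain_model
#' @export
read_sustain_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- event_grid(
    thresholds = as.list(doc$grid$thresholds),
    z_max = unlist(doc$grid$z_max),
    sigma = unlist(doc$grid$sigma)
  )
  seqs <- doc$sequence_event_ids
  if (is.matrix(seqs)) seqs <- split(seqs, seq_len(nrow(seqs)))
  seqs <- unname(seqs)
  sustain_fit(grid, lapply(seqs, as.integer),
              fractions = doc$fractions,
              loglik = doc$loglik %||% NA_real_, seed = doc$seed)
}

#' Export positional variance to CSV
#'
#' Long-format export: one row per (subtype, event, position) with the
#' posterior probability mass.
#'
#' @param pv A `positional_variance` object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_positional_variance <- function(pv, path) {
  readr::write_csv(tidy(pv), path)
  invisible(path)
}
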