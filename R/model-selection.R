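#' Cross-validated information criterion over subtype counts
#'
#' Ten-fold (by default) cross-validation at the subject level: for each
#' fold, the mixture model is fitted to the training subjects for every
#' candidate number of subtypes and the summed out-of-sample log-likelihood
#' is evaluated on the held-out subjects. The criterion is
#' `CVIC(C) = -2 * sum of test log-likelihoods`; folds are identical across
#' candidates so comparisons are paired.
#'
#' @param x A `zscore_panel` (patient baseline scans are used; subjects are
#'   the folding unit) or a z-score matrix with a `subject_ids` argument.
#' @param grid An `event_grid`.
#' @param n_subtypes_max Largest candidate C; candidates are `1:n_subtypes_max`.
#' @param n_folds Number of folds, default 10.
#' @param seed Integer seed controlling fold assignment and fitting.
#' @param n_starts Random restarts per fit (passed to [fit_mixture()]).
#' @param subject_ids Required when `x` is a matrix.
#' @param ... Further arguments to [fit_mixture()].
#' @return A tibble of class `cvic_table` with columns `n_subtypes`, `cvic`,
#'   `mean_fold_loglik`; the per-fold test log-likelihoods are in
#'   `attr(, "folds")`.
#' @export
crossval_cvic <- function(x, grid, n_subtypes_max = 2, n_folds = 10,
                          seed = NULL, n_starts = 24, subject_ids = NULL,
                          ...) {
  if (n_folds < 2) stop("`n_folds` must be >= 2.")
  if (inherits(x, "zscore_panel")) {
    keep <- x$scans$group == "patient" & x$scans$visit == 0
    X <- as_biomarker_matrix(x$z[keep, , drop = FALSE], grid)
    subject_ids <- x$scans$subject_id[keep]
  } else {
    X <- as_biomarker_matrix(x, grid)
    if (is.null(subject_ids)) subject_ids <- rownames(X) %||%
        as.character(seq_len(nrow(X)))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  subjects <- unique(subject_ids)
  fold_of <- stats::setNames(
    rep(seq_len(n_folds), length.out = length(subjects))[
      order(sample(length(subjects)))],
    subjects
  )
  sizes <- table(fold_of)
  if (any(sizes < 5)) stop("Every fold needs >= 5 subjects; smallest has ",
                           min(sizes), ".")

  rows <- list()
  for (fold in seq_len(n_folds)) {
    test <- subject_ids %in% names(fold_of)[fold_of == fold]
    for (C in seq_len(n_subtypes_max)) {
      fit <- fit_mixture(X[!test, , drop = FALSE], grid, n_subtypes = C,
                         n_starts = n_starts,
                         seed = sample.int(.Machine$integer.max, 1), ...)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_subtypes = C, fold = fold,
        test_loglik = dataset_loglik(X[test, , drop = FALSE], fit)
      )
    }
  }
  folds <- dplyr::bind_rows(rows)
  out <- dplyr::summarise(
    dplyr::group_by(folds, .data$n_subtypes),
    cvic = -2 * sum(.data$test_loglik),
    mean_fold_loglik = mean(.data$test_loglik),
    .groups = "drop"
  )
  attr(out, "folds") <- folds
  class(out) <- c("cvic_table", class(out))
  out
}

#' Choose the number of subtypes with a parsimony rule
#'
#' Starting from one subtype, each additional subtype is accepted when its
#' CVIC improves on the previous model by more than `cvic_margin` (strong
#' evidence on the deviance scale), or when the CVIC change is within the
#' margin but the mean per-fold test log-likelihood still strictly
#' improves. Otherwise the smaller (more parsimonious) model is kept.
#'
#' @param cvic_table A `cvic_table` from [crossval_cvic()], covering
#'   consecutive candidates from C = 1.
#' @param cvic_margin Strong-evidence margin on the CVIC scale, default 6.
#' @return List with `n_subtypes` (chosen C) and `rationale` (a tibble
#'   recording which rule fired at each step).
#' @export
select_subtype_count <- function(cvic_table, cvic_margin = 6) {
  tab <- dplyr::arrange(tibble::as_tibble(cvic_table), .data$n_subtypes)
  if (nrow(tab) == 0) stop("Empty CVIC table.")
  if (!all(tab$n_subtypes == seq_len(nrow(tab)))) {
    stop("CVIC table must cover consecutive subtype counts from 1.")
  }
  chosen <- 1L
  rationale <- list()
  for (i in seq_len(nrow(tab))[-1]) {
    improve <- tab$cvic[i - 1] - tab$cvic[i]
    ll_improve <- tab$mean_fold_loglik[i] > tab$mean_fold_loglik[i - 1]
    rule <- if (improve > cvic_margin) {
      "cvic_strong_improvement"
    } else if (improve >= -cvic_margin && ll_improve) {
      "within_margin_loglik_improves"
    } else {
      "parsimony_stop"
    }
    rationale[[length(rationale) + 1L]] <- tibble::tibble(
      n_subtypes = tab$n_subtypes[i], cvic_improvement = improve,
      mean_loglik_improves = ll_improve, rule = rule
    )
    if (rule == "parsimony_stop") break
    chosen <- tab$n_subtypes[i]
  }
  list(n_subtypes = chosen, rationale = dplyr::bind_rows(rationale))
}
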