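# C x (E+1) matrix of log P(c, k | x) terms (unnormalised):
# log f_c + log P(x | S_c, k) - log(E + 1).
joint_log_posterior <- function(X, fit) {
  grid <- fit$grid
  E <- grid$n_events
  C <- fit$n_subtypes
  lapply(seq_len(C), function(c) {
    stage_loglik_matrix(X, fit$sequences[[c]], grid) +
      log(fit$fractions[c]) - log(E + 1)
  })
}

#' Posterior over subtype and stage for one scan
#'
#' `P(c, k | x)` proportional to `f_c P(x | S_c, k) / (E + 1)`, normalised
#' over every (subtype, stage) pair, computed in log space.
#'
#' @param x Named numeric vector of z-scores covering the model biomarkers.
#' @param fit A `sustain_fit`.
#' @return A C x (E + 1) matrix of posterior probabilities summing to 1;
#'   columns are stages 0..E.
#' @export
posterior <- function(x, fit) {
  X <- as_biomarker_matrix(matrix(x, nrow = 1,
                                  dimnames = list(NULL, names(x))), fit$grid)
  L <- joint_log_posterior(X, fit)
  logp <- do.call(rbind, lapply(L, function(m) m[1, ]))
  if (any(!is.finite(logp) & logp > 0)) stop("Non-finite likelihood.")
  p <- exp(logp - logsumexp(logp))
  dimnames(p) <- list(subtype = seq_len(fit$n_subtypes),
                      stage = 0:fit$grid$n_events)
  p / sum(p)
}

#' Assign one scan to its maximum-likelihood subtype and stage
#'
#' The subtype is the argmax of the stage-summed posterior; the stage is
#' the argmax of the posterior within that subtype (ties broken toward the
#' lower index). The expected stage is the probability-weighted mean stage
#' over every stage of every subtype. Scans whose maximum-likelihood stage
#' is 0 (no detectable abnormality) or E (end stage) carry no subtype
#' information and are flagged not subtypable.
#'
#' @inheritParams posterior
#' @return One-row tibble with `ml_subtype`, `ml_stage`, `expected_stage`,
#'   `subtype_probability` and `subtypable`.
#' @export
assign_scan <- function(x, fit) {
  assignment_from_logs(
    joint_log_posterior(
      as_biomarker_matrix(matrix(x, nrow = 1,
                                 dimnames = list(NULL, names(x))), fit$grid),
      fit),
    fit)[1, ]
}

assignment_from_logs <- function(L, fit) {
  E <- fit$grid$n_events
  C <- fit$n_subtypes
  n <- nrow(L[[1]])
  if (n == 0) {
    return(tibble::tibble(ml_subtype = integer(), ml_stage = integer(),
                          expected_stage = numeric(),
                          subtype_probability = numeric(),
                          subtypable = logical()))
  }
  flat <- do.call(cbind, L)                      # n x (C*(E+1))
  if (any(!is.finite(apply(flat, 1, max)))) stop("Non-finite likelihoods.")
  norm <- row_logsumexp(flat)
  post <- exp(flat - norm)                       # rows sum to 1
  subtype_mass <- vapply(seq_len(C), function(c) {
    rowSums(post[, (c - 1) * (E + 1) + seq_len(E + 1), drop = FALSE])
  }, numeric(n))
  subtype_mass <- matrix(subtype_mass, nrow = n)
  ml_subtype <- max.col(subtype_mass, ties.method = "first")
  ml_stage <- vapply(seq_len(n), function(j) {
    c <- ml_subtype[j]
    which.max(post[j, (c - 1) * (E + 1) + seq_len(E + 1)]) - 1L
  }, integer(1))
  stages <- rep(0:E, times = C)
  expected_stage <- as.numeric(post %*% stages)
  tibble::tibble(
    ml_subtype = ml_subtype,
    ml_stage = ml_stage,
    expected_stage = expected_stage,
    subtype_probability = subtype_mass[cbind(seq_len(n), ml_subtype)],
    subtypable = !(ml_stage %in% c(0L, E))
  )
}

#' Assign every scan in a panel under a frozen model
#'
#' Applies the fitted (or ground-truth) model to all scans — controls,
#' patients, baseline and follow-up alike — without refitting. Assignments
#' are a pure function of each scan's z-scores, so batch and single-scan
#' processing agree exactly.
#'
#' @param panel A `zscore_panel` or a z-score matrix covering the model
#'   biomarkers.
#' @param fit A `sustain_fit`.
#' @return Tibble with one row per scan: scan metadata (when available),
#'   `ml_subtype`, `ml_stage`, `expected_stage`, `subtype_probability`,
#'   `subtypable`. The number of non-subtypable scans is reported as a
#'   message.
#' @export
assign_cohort <- function(panel, fit) {
  if (inherits(panel, "zscore_panel")) {
    X <- as_biomarker_matrix(panel$z, fit$grid)
    meta <- panel$scans
  } else {
    X <- as_biomarker_matrix(panel, fit$grid)
    meta <- tibble::tibble(scan_id = rownames(X) %||%
                             sprintf("scan_%04d", seq_len(nrow(X))))
  }
  out <- assignment_from_logs(joint_log_posterior(X, fit), fit)
  res <- dplyr::bind_cols(tibble::as_tibble(meta[seq_len(nrow(out)), ,
                                                 drop = FALSE]), out)
  if (nrow(res) > 0) {
    message(sum(!res$subtypable), " of ", nrow(res),
            " scan(s) not subtypable (stage 0 or end stage).")
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
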