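#' @importFrom stats dnorm setNames
NULL

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

row_logsumexp <- function(M) {
  m <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  out <- m + log(rowSums(exp(M - m)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# Precomputed per-data quantities reused across many candidate sequences.
ll_ctx <- function(X, grid) {
  sig <- unname(grid$sigma[grid$biomarkers])
  Xs <- sweep(X, 2, sig, "/")
  list(Xs = Xs, rs2 = rowSums(Xs^2),
       const = -sum(log(sig)) - length(sig) * 0.5 * log(2 * pi),
       sig = sig, z_max = unname(grid$z_max[grid$biomarkers]))
}

ctx_stage_loglik <- function(ctx, ordering, grid) {
  .stage_loglik_cpp(ctx$Xs, ctx$rs2, ctx$const, ctx$sig,
                    grid$bm_events, grid$bm_z, ctx$z_max,
                    as.integer(ordering))
}

ctx_marginal <- function(ctx, ordering, grid) {
  as.numeric(.marginal_cpp(ctx$Xs, ctx$rs2, ctx$const, ctx$sig,
                           grid$bm_events, grid$bm_z, ctx$z_max,
                           as.integer(ordering)))
}

# Coerce input to an n x I matrix with columns in grid biomarker order.
as_biomarker_matrix <- function(x, grid) {
  X <- if (inherits(x, "zscore_panel")) panel_matrix(x) else as.matrix(x)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(grid$biomarkers)) {
      stop("Unnamed z-score matrix must have one column per grid biomarker.")
    }
    colnames(X) <- grid$biomarkers
  }
  missing <- setdiff(grid$biomarkers, colnames(X))
  if (length(missing)) {
    stop("z-score input lacks biomarkers: ", paste(missing, collapse = ", "))
  }
  X <- X[, grid$biomarkers, drop = FALSE]
  if (anyNA(X)) stop("z-score input contains missing values; scans with missing biomarkers must be excluded upstream.")
  X
}

# n x (E + 1) matrix of log P(x_j | S, k) for stages k = 0..E under the
# Gaussian observation model around the piecewise-linear trajectory.
stage_loglik_matrix <- function(X, ordering, grid) {
  ctx_stage_loglik(ll_ctx(X, grid), ordering, grid)
}

#' Stage-conditional data likelihood
#'
#' Density of one scan's biomarker z-scores given a subtype sequence and a
#' model stage: independent Gaussians centred on the piecewise-linear
#' expected trajectory, \eqn{\prod_i N(x_i; g_i(k), \sigma_i)}.
#'
#' @param x Named numeric vector of z-scores, one per grid biomarker.
#' @param ordering Integer event sequence.
#' @param grid An `event_grid`.
#' @param stage Integer stage in `0..E`.
#' @param log Return the log density? Default `FALSE`.
#' @return Scalar (log-)density.
#' @export
stage_likelihood <- function(x, ordering, grid, stage, log = FALSE) {
  E <- grid$n_events
  if (length(stage) != 1 || stage < 0 || stage > E) {
    stop("`stage` must be a single integer in [0, ", E, "].")
  }
  X <- as_biomarker_matrix(matrix(x, nrow = 1,
                                  dimnames = list(NULL, names(x))), grid)
  ll <- stage_loglik_matrix(X, ordering, grid)[1, stage + 1L]
  if (log) ll else exp(ll)
}

#' Stage-marginal subject likelihood
#'
#' Marginalises the stage-conditional likelihood over a uniform prior on
#' stages 0..E: \eqn{P(x | S) = \frac{1}{E+1}\sum_{k=0}^{E} P(x | S, k)},
#' computed with log-sum-exp.
#'
#' @inheritParams stage_likelihood
#' @return Scalar (log-)marginal likelihood.
#' @export
subject_marginal <- function(x, ordering, grid, log = FALSE) {
  X <- as_biomarker_matrix(matrix(x, nrow = 1,
                                  dimnames = list(NULL, names(x))), grid)
  L <- stage_loglik_matrix(X, ordering, grid)
  ll <- logsumexp(L[1, ]) - log(grid$n_events + 1)
  if (log) ll else exp(ll)
}

# log P(x_j | S) for all subjects at once.
marginal_loglik_vector <- function(X, ordering, grid) {
  ctx_marginal(ll_ctx(X, grid), ordering, grid)
}

#' Construct a subtype-and-stage model object
#'
#' Bundles an event grid with one sequence per subtype and mixture fractions.
#' Fitted models are produced by [fit_mixture()]; this constructor also lets
#' a known ground-truth model (e.g. from the synthetic generator) be used
#' directly for staging and assignment.
#'
#' @param grid An `event_grid`.
#' @param sequences List of integer event sequences, one per subtype.
#' @param fractions Mixture fractions; positive, summing to 1. Default
#'   uniform.
#' @param loglik Optional maximised data log-likelihood.
#' @param seed Optional seed record.
#' @return An object of class `sustain_fit`.
#' @export
sustain_fit <- function(grid, sequences, fractions = NULL, loglik = NA_real_,
                        seed = NULL) {
  if (!inherits(grid, "event_grid")) stop("`grid` must be an event_grid.")
  if (!is.list(sequences) || length(sequences) < 1) {
    stop("`sequences` must be a non-empty list of orderings.")
  }
  for (s in sequences) validate_sequence(s, grid)
  C <- length(sequences)
  if (is.null(fractions)) fractions <- rep(1 / C, C)
  if (length(fractions) != C || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be positive and sum to 1 (one per subtype).")
  }
  structure(
    list(grid = grid, sequences = sequences,
         fractions = fractions / sum(fractions),
         loglik = loglik, n_subtypes = C, seed = seed, mcmc = NULL),
    class = "sustain_fit"
  )
}

#' @export
print.sustain_fit <- function(x, ...) {
  cat("<sustain_fit> ", x$n_subtypes, " subtype(s), ",
      x$grid$n_events, " events, fractions: ",
      paste(sprintf("%.3f", x$fractions), collapse = "/"),
      ", loglik: ", format(x$loglik), "\n", sep = "")
  invisible(x)
}

#' Mixture data log-likelihood
#'
#' Total log-likelihood of a z-score data set under a subtype mixture:
#' \eqn{\sum_j \log \sum_c f_c P(x_j | S_c)}, with stages marginalised
#' uniformly within each subtype.
#'
#' @param x A `zscore_panel` or numeric matrix (scans x biomarkers) with
#'   columns named after the grid biomarkers.
#' @param fit A `sustain_fit`.
#' @return Scalar log-likelihood.
#' @export
dataset_loglik <- function(x, fit) {
  X <- as_biomarker_matrix(x, fit$grid)
  mixture_loglik(X, fit$sequences, fit$fractions, fit$grid)
}

mixture_loglik <- function(X, sequences, fractions, grid) {
  per <- vapply(seq_along(sequences), function(c) {
    marginal_loglik_vector(X, sequences[[c]], grid) + log(fractions[c])
  }, numeric(nrow(X)))
  per <- matrix(per, nrow = nrow(X))
  sum(row_logsumexp(per))
}
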