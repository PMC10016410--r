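# Weighted stage-marginal objective for a single sequence:
#   sum_j w_j * log P(x_j | S)   (uniform stage prior inside the marginal)
weighted_objective <- function(ctx, ordering, grid, w) {
  sum(w * ctx_marginal(ctx, ordering, grid))
}

# Greedy event re-insertion to convergence (compiled inner loop; sweep
# order uses R's RNG so seeds behave as usual).
greedy_to_convergence <- function(ctx, ordering, grid, w, max_passes = 100) {
  res <- .greedy_cpp(ctx$Xs, ctx$rs2, ctx$const, ctx$sig, grid$bm_events,
                     grid$bm_z, ctx$z_max, grid$prev_event, grid$next_event,
                     as.integer(ordering), w, as.integer(max_passes))
  list(ordering = as.integer(res$ordering), objective = res$objective)
}

#' Optimise a single event sequence by greedy search with random restarts
#'
#' From each of `n_starts` random valid starting sequences, repeatedly
#' sweeps over the events, re-inserting each at the position (compatible
#' with within-biomarker threshold order) that maximises the
#' stage-marginalised data log-likelihood, until a full sweep yields no
#' improvement. Returns the best solution across starts; the returned
#' log-likelihood is never below that of any start.
#'
#' @param x A `zscore_panel` (patient baseline scans are used) or a numeric
#'   matrix of z-scores (scans x biomarkers).
#' @param grid An `event_grid`.
#' @param n_starts Number of random starting sequences, default 24.
#' @param seed Integer seed controlling the restarts (and the sweep order);
#'   identical seeds give identical results.
#' @param weights Optional non-negative per-scan weights (used internally by
#'   the mixture EM).
#' @return List with `ordering`, `loglik`, and `start_logliks`.
#' @export
optimize_sequence_greedy <- function(x, grid, n_starts = 24, seed = NULL,
                                     weights = NULL) {
  if (grid$n_events < 1) stop("Event grid is empty.")
  X <- fitting_matrix(x, grid)
  if (nrow(X) == 0) stop("No scans to fit.")
  w <- if (is.null(weights)) rep(1, nrow(X)) else weights
  if (!is.null(seed)) withr::local_seed(seed)
  ctx <- ll_ctx(X, grid)

  best <- NULL
  start_objs <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    res <- greedy_to_convergence(ctx, random_sequence(grid), grid, w)
    start_objs[s] <- res$objective
    if (is.null(best) || res$objective > best$objective) best <- res
  }
  list(ordering = best$ordering, loglik = best$objective,
       start_logliks = start_objs)
}

# Panel -> patient baseline matrix; matrix passes through.
fitting_matrix <- function(x, grid) {
  if (inherits(x, "zscore_panel")) {
    as_biomarker_matrix(panel_matrix(x, "patient_baseline"), grid)
  } else {
    as_biomarker_matrix(x, grid)
  }
}

# Responsibilities r_{jc} proportional to f_c P(x_j | S_c); also the mixture
# log-likelihood, reusing the per-subtype marginal vectors.
e_step <- function(ctx, sequences, fractions, grid) {
  C <- length(sequences)
  n <- nrow(ctx$Xs)
  M <- vapply(seq_len(C), function(c) {
    ctx_marginal(ctx, sequences[[c]], grid) + log(fractions[c])
  }, numeric(n))
  M <- matrix(M, nrow = n)
  norm <- row_logsumexp(M)
  list(resp = exp(M - norm), loglik = sum(norm))
}

em_refine <- function(ctx, sequences, fractions, grid, tol = 1e-6,
                      max_iter = 100, max_passes = 100) {
  C <- length(sequences)
  es <- e_step(ctx, sequences, fractions, grid)
  ll <- es$loglik
  for (it in seq_len(max_iter)) {
    resp <- es$resp
    # empty-cluster rescue: re-seed from the worst-fit subjects
    counts <- colSums(resp)
    for (c in which(counts < 1e-8)) {
      message("Empty subtype ", c, " during EM; re-seeded from worst-fit scans.")
      n <- nrow(ctx$Xs)
      fitvec <- row_logsumexp(matrix(vapply(seq_len(C), function(cc) {
        ctx_marginal(ctx, sequences[[cc]], grid) + log(fractions[cc])
      }, numeric(n)), nrow = n))
      worst <- order(fitvec)[seq_len(max(2L, ceiling(n / 10)))]
      resp[, c] <- 0
      resp[worst, c] <- 1
      resp <- resp / rowSums(resp)
    }
    fractions <- pmax(colMeans(resp), 1e-12)
    fractions <- fractions / sum(fractions)
    for (c in seq_len(C)) {
      sequences[[c]] <- greedy_to_convergence(
        ctx, sequences[[c]], grid, resp[, c], max_passes = max_passes
      )$ordering
    }
    es <- e_step(ctx, sequences, fractions, grid)
    if (es$loglik - ll < tol) { ll <- es$loglik; break }
    ll <- es$loglik
  }
  list(sequences = sequences, fractions = fractions, loglik = ll)
}

#' Fit the subtype-and-stage mixture model
#'
#' Hierarchical fit: the single-subtype solution comes from
#' [optimize_sequence_greedy()]; each additional subtype is introduced by
#' splitting, in turn, every existing cluster (hard-assigning its members by
#' maximum responsibility, randomly bipartitioning them, fitting a sequence
#' to each half) and refining the resulting C-subtype model by
#' expectation-maximisation — responsibilities in the E-step, fraction
#' updates and responsibility-weighted greedy sequence moves in the M-step —
#' until the log-likelihood gain falls below `tol`. The best-scoring split
#' is adopted; if no split improves on the (C-1)-subtype model, a duplicated
#' sequence with split fractions is returned so the fitted log-likelihood is
#' never below the smaller model's.
#'
#' @inheritParams optimize_sequence_greedy
#' @param n_subtypes Number of subtypes C >= 1.
#' @param n_starts Random restarts for the single-subtype fit, default 24.
#' @param n_split_tries Independent random bipartitions attempted per
#'   cluster split (default `n_starts`). Each try fits its two halves from a
#'   single random start: keeping the half-fits deliberately under-restarted
#'   preserves the diversity needed for the EM refinement to discover a
#'   minority subtype, and the best refined likelihood across tries is kept.
#' @param tol EM convergence tolerance on the log-likelihood, default 1e-6.
#' @param max_iter Maximum EM iterations per split, default 100.
#' @return A [sustain_fit()] object with fitted sequences, fractions, and
#'   the maximised data log-likelihood.
#' @export
fit_mixture <- function(x, grid, n_subtypes = 1, n_starts = 24,
                        n_split_tries = n_starts, seed = NULL,
                        tol = 1e-6, max_iter = 100) {
  if (n_subtypes < 1) stop("`n_subtypes` must be >= 1.")
  X <- fitting_matrix(x, grid)
  if (nrow(X) < 10 * n_subtypes) {
    stop("Need at least ", 10 * n_subtypes, " scans to fit ", n_subtypes,
         " subtype(s); got ", nrow(X), ".")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  ctx <- ll_ctx(X, grid)

  single <- optimize_sequence_greedy(X, grid, n_starts = n_starts)
  sequences <- list(single$ordering)
  fractions <- 1
  loglik <- single$loglik

  C <- 1L
  while (C < n_subtypes) {
    best <- NULL
    for (target in seq_len(C)) {
      resp <- e_step(ctx, sequences, fractions, grid)$resp
      members <- which(max.col(resp, ties.method = "first") == target)
      if (length(members) < 4) next
      for (try in seq_len(n_split_tries)) {
        half <- sample(members, floor(length(members) / 2))
        other <- setdiff(members, half)
        s1 <- greedy_to_convergence(
          ll_ctx(X[half, , drop = FALSE], grid), random_sequence(grid),
          grid, rep(1, length(half)))$ordering
        s2 <- greedy_to_convergence(
          ll_ctx(X[other, , drop = FALSE], grid), random_sequence(grid),
          grid, rep(1, length(other)))$ordering
        cand_seq <- append(sequences[-target], list(s1, s2))
        cand_frac <- c(fractions[-target],
                       fractions[target] * c(length(half), length(other)) /
                         length(members))
        # short EM to score the try; only the winner is refined fully
        refined <- em_refine(ctx, cand_seq, cand_frac, grid, tol = tol,
                             max_iter = 5)
        if (is.null(best) || refined$loglik > best$loglik) best <- refined
      }
    }
    if (!is.null(best)) {
      best <- em_refine(ctx, best$sequences, best$fractions, grid,
                        tol = tol, max_iter = max_iter)
    }
    if (is.null(best) || best$loglik < loglik - 1e-6) {
      # no split improves: duplicate the largest cluster (equivalent model)
      big <- which.max(fractions)
      sequences <- append(sequences, sequences[big])
      fractions <- c(fractions, fractions[big] / 2)
      fractions[big] <- fractions[big] / 2
    } else {
      sequences <- best$sequences
      fractions <- best$fractions
      loglik <- best$loglik
    }
    loglik <- mixture_loglik(X, sequences, fractions, grid)
    C <- C + 1L
  }

  fit <- sustain_fit(grid, sequences, fractions, loglik = loglik, seed = seed)
  fit$n_scans <- nrow(X)
  fit
}
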